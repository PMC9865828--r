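# Amino-acid reference tables used by the sequence encoders. Shipped as
# plain exported constants so they are transparent and overridable.

#' The 20 standard amino-acid one-letter codes
#' @format Character vector of length 20, alphabetical.
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Chou-style property table for PseAAC correlation factors
#'
#' Hydrophobicity, hydrophilicity (Hopp-Woods) and side-chain mass for the
#' 20 standard residues; the classic triple used to build the
#' sequence-order correlation factors of pseudo amino acid composition.
#' Rows are properties, columns residues. Values are standardized
#' internally before use.
#'
#' @format Numeric matrix, 3 x 20.
#' @export
PSEAAC_PROPERTIES <- local({
  m <- rbind(
    hydrophobicity = c(
      A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
      G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
      M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
      S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26),
    hydrophilicity = c(
      A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
      G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
      M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
      S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    side_chain_mass = c(
      A =  15, C =  47, D =  59, E =  73, F =  91,
      G =   1, H =  82, I =  57, K =  73, L =  57,
      M =  75, N =  58, P =  42, Q =  72, R = 101,
      S =  31, T =  45, V =  43, W = 130, Y = 107)
  )
  m[, AA_LETTERS]
})

#' Physicochemical scales for autocorrelation descriptors
#'
#' Eight widely used per-residue scales: Kyte-Doolittle hydropathy,
#' Hopp-Woods hydrophilicity, side-chain mass, isoelectric point, residue
#' volume, Grantham polarity, average flexibility and Zimmerman bulkiness.
#' Each scale is z-scored over the 20 residues before the autocorrelation
#' sums are taken, so the absolute units never matter.
#'
#' @format Numeric matrix, 8 x 20 (properties x residues).
#' @export
AD_PROPERTIES <- local({
  m <- rbind(
    hydropathy = c(
      A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
      G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
      M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
      S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3),
    hydrophilicity = c(
      A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
      G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
      M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
      S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    side_chain_mass = c(
      A =  15, C =  47, D =  59, E =  73, F =  91,
      G =   1, H =  82, I =  57, K =  73, L =  57,
      M =  75, N =  58, P =  42, Q =  72, R = 101,
      S =  31, T =  45, V =  43, W = 130, Y = 107),
    isoelectric_point = c(
      A = 6.00, C = 5.07, D = 2.77, E = 3.22, F = 5.48,
      G = 5.97, H = 7.59, I = 6.02, K = 9.74, L = 5.98,
      M = 5.74, N = 5.41, P = 6.30, Q = 5.65, R = 10.76,
      S = 5.68, T = 5.60, V = 5.96, W = 5.89, Y = 5.66),
    volume = c(
      A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
      G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
      M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
      S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6),
    polarity = c(
      A =  8.1, C =  5.5, D = 13.0, E = 12.3, F =  5.2,
      G =  9.0, H = 10.4, I =  5.2, K = 11.3, L =  4.9,
      M =  5.7, N = 11.6, P =  8.0, Q = 10.5, R = 10.5,
      S =  9.2, T =  8.6, V =  5.9, W =  5.4, Y =  6.2),
    flexibility = c(
      A = 0.357, C = 0.346, D = 0.511, E = 0.497, F = 0.314,
      G = 0.544, H = 0.323, I = 0.462, K = 0.466, L = 0.365,
      M = 0.295, N = 0.463, P = 0.509, Q = 0.493, R = 0.529,
      S = 0.507, T = 0.444, V = 0.386, W = 0.305, Y = 0.420),
    bulkiness = c(
      A = 11.50, C = 13.46, D = 11.68, E = 13.57, F = 19.80,
      G =  3.40, H = 13.69, I = 21.40, K = 15.71, L = 21.40,
      M = 16.25, N = 12.82, P = 17.43, Q = 14.45, R = 14.28,
      S =  9.47, T = 15.77, V = 21.57, W = 21.67, Y = 18.03)
  )
  m[, AA_LETTERS]
})

#' Conjoint-triad class map
#'
#' The standard partition of the 20 amino acids into 7 classes by dipole
#' moment and side-chain volume: \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\},
#' \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\}.
#'
#' @format Named integer vector: residue -> class in 1..7.
#' @export
CT_CLASSES <- c(
  A = 1L, G = 1L, V = 1L,
  I = 2L, L = 2L, F = 2L, P = 2L,
  Y = 3L, M = 3L, T = 3L, S = 3L,
  H = 4L, N = 4L, Q = 4L, W = 4L,
  R = 5L, K = 5L,
  D = 6L, E = 6L,
  C = 7L
)[AA_LETTERS]
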