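# Shared tiny fixtures, built once per test run.

toy_smiles <- c("CCO", "CCN", "c1ccccc1C", "CCOC", "CC(C)O",
                "c1ccncc1", "CCCl", "CC(=O)O", "c1ccccc1O", "CCCC")

toy_corpus <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- ligandgen::make_corpus(toy_smiles)
    value
  }
})

toy_vocab <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- ligandgen::build_vocabulary(toy_corpus())
    value
  }
})

tiny_gpt <- function(vocab = toy_vocab(), n_layers = 1L, n_heads = 1L,
                     embed_dim = 4L, condition_dim = 8L, dropout = 0,
                     seed = 3L, max_len = 40L) {
  ligandgen::smiles_gpt(
    ligandgen::generator_config(n_layers = n_layers, n_heads = n_heads,
                                embed_dim = embed_dim,
                                ff_hidden = 4L * embed_dim,
                                max_len = max_len,
                                condition_dim = condition_dim,
                                dropout = dropout, seed = seed),
    vocab)
}
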