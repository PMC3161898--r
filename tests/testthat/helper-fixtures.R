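# Shared fixture cache: the phosphate catalog is used by several test
# files and is built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

pho_state_matrix_cached <- function() {
  if (is.null(.fixture_cache$pho_sm))
    .fixture_cache$pho_sm <- compile_state_matrix(pho_regulon()$experiments)
  .fixture_cache$pho_sm
}

pho_catalog_cached <- function() {
  if (is.null(.fixture_cache$pho_cat))
    .fixture_cache$pho_cat <- build_catalog(pho_state_matrix_cached())
  .fixture_cache$pho_cat
}

toy_catalog_cached <- function() {
  if (is.null(.fixture_cache$toy_cat))
    .fixture_cache$toy_cat <- build_catalog(compile_state_matrix(toy_net()$experiments))
  .fixture_cache$toy_cat
}

# small two-step chain whose pair invariants make every column unique
unique_chain_experiments <- function() {
  vals <- rbind(c(1L, 0L, 1L, 0L),
                c(0L, 1L, 1L, 0L),
                c(0L, 1L, 0L, 1L),
                c(0L, 1L, 0L, 1L))
  colnames(vals) <- c("A", "B", "C", "D")
  list(experiment(vals, id = "chain"))
}
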