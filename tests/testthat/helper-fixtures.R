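# Shared test fixtures. Everything is generated in code; expensive objects
# (the planted-motif benchmark and trained models) are built once per test
# run and memoised in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a toy 2-column PWM used across pwm tests: consensus "AC"
toy_pwm_file <- function() {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(">TOY0001.1 toy",
               "A [ 9 0 ]",
               "C [ 0 9 ]",
               "G [ 0 0 ]",
               "T [ 1 1 ]"), path)
  path
}

# genome with one 60 bp chromosome for io tests
toy_genome <- function(seq = "AACCGGTT") {
  g <- list(chr1 = seq)
  attr(g, "lengths") <- c(chr1 = nchar(seq))
  class(g) <- "genome"
  g
}

# small desk-scale benchmark: ~160 windows on 2 x 60 kb, 400 bp windows.
# Used by unit tests that need labeled windows but not a trained model.
small_fixture <- function() {
  cache_get("small_fixture", function() {
    spec <- fixture_spec(seed = 402, n_chroms = 2L, chrom_length = 60000L,
                         n_positive = 40L, n_type1 = 40L, n_type2 = 40L,
                         n_type3 = 40L)
    fx <- plant_windows(make_background_genome(spec), spec)
    fx$spec <- spec
    fx
  })
}

small_manifest <- function() {
  cache_get("small_manifest", function() {
    fx <- small_fixture()
    build_dataset(fx$genome, fx$peaks$ctcf, fx$peaks$chiapet, fx$peaks$atac,
                  fx$spec$primary_motif, window_length = 400L, seed = 7)
  })
}

# a very small architecture for gradient-level tests (fast single passes)
micro_config <- function(dropout = 0) {
  model_config(input_length = 64L,
               blocks = list(list(filters = 3L, kernel = 31L, pool = 2L),
                             list(filters = 4L, kernel = 5L, pool = 2L),
                             list(filters = 5L, kernel = 3L, pool = 2L)),
               dense = c(6L, 4L, 1L), dropout = dropout)
}
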