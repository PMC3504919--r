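# Shared fixtures, memoized so expensive builds run once per session.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small scenario pair for unit tests (~1 s to build)
small_params <- function(seed = 11, ...) {
  sim_params(K = 15, H = 100, N = 80, M = 600, chrom_length_bp = 2e6,
             n_hotspots = 12, seed = seed, ...)
}

small_fixture <- function() memo("small_fixture", build_fixture(small_params()))

# the reference evaluation conditions (seed 7); shared by the acceptance tests
reference_fixture <- function() memo("reference_fixture",
                                     build_fixture(sim_params(seed = 7)))

reference_report <- function() memo("reference_report", {
  fx <- reference_fixture()
  run_scenario(fx$train, fx$test, seed = 42)
})

# random nonnegative 3x3 tables, occasionally sparse
random_tables <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tab <- matrix(stats::rpois(9, lambda = sample(c(1, 5, 40), 1)), 3, 3)
    if (stats::runif(1) < 0.3) tab[sample(9, 3)] <- 0
    tab
  })
}

# independent Cohen's kappa oracle (e1071, written against Table-style input)
kappa_oracle <- function(tab) e1071::classAgreement(tab)$kappa

# random posterior matrix with rows summing to one
random_posteriors <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(stats::rgamma(3 * n, shape = 1), n, 3)
  p / rowSums(p)
}
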