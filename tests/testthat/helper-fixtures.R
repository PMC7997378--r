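## shared fixture builders for the test suite

toy_ff <- function(value = 1, id = "TOY") ff_table(NULL, stats::setNames(value, id))

random_beads <- function(n, seed, sd = 5, ids = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(3 * n, sd = sd), n, 3)
  if (is.null(ids)) ids <- rep("TOY", n)
  bead_structure(X, ids)
}

## brute-force double-loop Debye sum, independent of the package kernel
brute_debye <- function(X, f, q) {
  n <- nrow(X)
  vapply(q, function(qq) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      r <- sqrt(sum((X[i, ] - X[j, ])^2))
      s <- s + f[i] * f[j] * (if (qq * r < 1e-12) 1 else sin(qq * r) / (qq * r))
    }
    s
  }, numeric(1))
}

## ubiquitin sequence (1-letter); the K63-linked dimer construct used for
## the bead-count worked example is distal (K63R) + proximal (extra D77)
UBIQUITIN_SEQ <- "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"

k63_ub2_residues <- function() {
  ub <- strsplit(UBIQUITIN_SEQ, "")[[1]]
  distal <- ub; distal[63] <- "R"
  proximal <- c(ub, "D")
  paste(c(distal, proximal), collapse = "")
}

## two-state dumbbell recovery setup shared by sampler and acceptance tests
dumbbell_recovery_inputs <- function(p = 0.7, seed_ens = 11, seed_noise = 12) {
  sys <- make_dumbbell_system()
  xc <- make_dumbbell_system(start = "compact")$x
  ens <- make_two_state_ensemble(xc, sys$x, p = p, n_frames = 400,
                                 jitter = 0.3, masses = sys$masses,
                                 seed = seed_ens)
  q <- seq(0.05, 0.20, length.out = 7)
  syn <- make_synthetic_saxs(ens, q = q, noise_rel = 0.005, seed = seed_noise)
  rs <- structure(list(q = q, intensity = syn$curve$intensity,
                       error = syn$curve$error, window = 1L),
                  class = "restraint_set")
  list(sys = sys, restraints = rs, truth = syn$true,
       groupA = attr(sys, "groupA"), groupB = attr(sys, "groupB"))
}
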