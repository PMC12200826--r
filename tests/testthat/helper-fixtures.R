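# Shared fixtures, built in code at test time.

# A no-peak single-stage parameter set for aperiodic-only simulations.
aperiodic_only_params <- function(exponent, offset = 1,
                                  montage = default_montage()[1, ,
                                                              drop = FALSE]) {
  eeg_sim_params(
    montage = montage,
    stages = list(W = list(offset = offset, exponent = exponent,
                           peaks = data.frame(centre = numeric(0),
                                              height = numeric(0),
                                              width = numeric(0))))
  )
}

# Analytic spectrum on the standard 1-45 Hz grid: aperiodic 10^b / f^x
# plus optional Gaussian bumps in log10 space.
model_spectrum <- function(b, x, peaks = NULL, df = 0.2) {
  f <- seq(1, 45, by = df)
  logp <- b - x * log10(f)
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      logp <- logp + peaks$height[i] *
        exp(-(f - peaks$centre[i])^2 / (2 * peaks$sd[i]^2))
    }
  }
  list(frequencies = f, power = 10^logp)
}

# Bernoulli series with a generative sigmoid switch, on the hard-trial
# positions of a standard session layout (about 3.3 trials apart).
sigmoid_series <- function(y_min, y_max, m, t_s, seed,
                           positions = NULL) {
  set.seed(seed)
  if (is.null(positions)) positions <- sort(sample(201:800, 180))
  p <- y_min + (y_max - y_min) / (1 + exp(-m * (positions - t_s)))
  list(correct = stats::runif(length(positions)) < p,
       positions = positions)
}

# Exhaustive two-group permutation oracle for the max-cluster-mass test:
# enumerates all assignments of n1 subjects to group 1 and returns the
# exact p-value for each observed cluster mass.
exhaustive_cluster_p <- function(data, n1, adjacency, cluster_alpha) {
  n <- dim(data)[1]
  combos <- utils::combn(n, n1)
  X <- matrix(aperm(data, c(1, 3, 2)), nrow = n)
  n_ch <- dim(data)[2]; n_bins <- dim(data)[3]
  neighbours <- napinsight:::.element_neighbours(adjacency, n_ch, n_bins)
  masses_of <- function(g1) {
    g2 <- setdiff(seq_len(n), g1)
    napinsight:::.cluster_masses(X, NULL, "t",
                                 list(g1, g2), neighbours,
                                 cluster_alpha)$masses
  }
  obs <- masses_of(seq_len(n1))
  null_max <- apply(combos, 2, function(g1) {
    m <- masses_of(g1)
    if (length(m)) max(abs(m)) else 0
  })
  vapply(obs, function(m) mean(null_max >= abs(m)), numeric(1))
}
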