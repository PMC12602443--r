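# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately use different code paths (explicit loops,
# prod()^(1/n) geometric means) from the package implementation.

# Step-up Benjamini-Hochberg straight from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(vapply(i:m, function(j) m * ps[j] / j, numeric(1)), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Median-of-ratios size factors, loop form with a hand-rolled median.
size_factor_oracle <- function(counts) {
  ng <- nrow(counts); ns <- ncol(counts)
  allpos <- apply(counts, 1L, function(r) all(r > 0))
  geo <- numeric(ng)
  for (g in which(allpos)) geo[g] <- exp(mean(log(counts[g, ])))
  mid <- function(x) {  # sort-and-pick median
    x <- sort(x); n <- length(x)
    if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
  }
  sf <- numeric(ns)
  for (j in seq_len(ns)) sf[j] <- mid(counts[allpos, j] / geo[allpos])
  sf / prod(sf)^(1 / ns)
}

rand_counts <- function(ng = 50L, ns = 4L, lambda = 100) {
  m <- matrix(rpois(ng * ns, lambda), nrow = ng,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("s%02d", seq_len(ns))))
  storage.mode(m) <- "integer"
  m
}

# Two-group count matrix + sheet for de_core tests.
two_group_data <- function(ng = 200L, n = 3L, mu = NULL, disp = 0.05,
                           lfc = rep(0, ng), seed = 1L) {
  set.seed(seed)
  if (is.null(mu)) mu <- exp(rnorm(ng, 4, 1.5)) + 1
  sf <- runif(2L * n, 0.7, 1.4)
  counts <- sapply(seq_len(2L * n), function(j) {
    eff <- if (j > n) 2^lfc else rep(1, ng)
    rnbinom(ng, mu = mu * eff * sf[j], size = 1 / disp)
  })
  dimnames(counts) <- list(sprintf("g%04d", seq_len(ng)),
                           c(sprintf("sham_%d", seq_len(n)),
                             sprintf("cm_%d", seq_len(n))))
  storage.mode(counts) <- "integer"
  sheet <- data.frame(sample_id = colnames(counts),
                      condition = rep(c("sham", "cm"), each = n),
                      organ = "spleen", stringsAsFactors = FALSE)
  list(counts = counts, sheet = sheet)
}

# An fc_fit stand-in with known thresholds, for classification tests.
fixed_fit <- function(center = 0, width = 0.5, model = "gaussian") {
  structure(list(model = model, center = center, width = width,
                 amplitude = 100, sse = 0, converged = TRUE),
            class = "fc_fit")
}

# Histogram object from explicit bins (counts may be non-integer for
# noiseless fit-recovery checks).
make_hist <- function(bin_left, count, bin_width = 0.1) {
  structure(data.frame(bin_left = bin_left, count = count),
            class = c("fc_histogram", "data.frame"),
            bin_width = bin_width, n_dropped = 0L)
}

bundled_panel <- function() {
  read_panel(system.file("extdata", "iei_panel_485_synthetic.tsv",
                         package = "reprogR"))
}
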