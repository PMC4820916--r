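# Shared fixtures, built in code.

species_names <- function(n) sprintf("lipid_%03d", seq_len(n))

# Three-generation pedigree covering the standard relationship classes:
# grandparents, their two children (one married in), grandchildren,
# a half-sibling and a cousin branch.
relationship_pedigree <- function() {
  tibble::tibble(
    id     = c("gf", "gm", "f", "m", "u", "ua", "c1", "c2", "hm", "h1",
               "k1"),
    father = c(NA,   NA,   "gf", NA, "gf", NA,  "f",  "f",  NA,  "f",
               "u"),
    mother = c(NA,   NA,   "gm", NA, "gm", NA,  "m",  "m",  NA,  "hm",
               "ua"),
    sex    = c(1,    2,    1,    2,  1,    2,   1,    2,    2,   1,
               2))
}

# Small cohort with exact times, optional planted effect on `x`.
toy_survival <- function(n = 150, beta = 0.7, base = 0.08, cens = NULL,
                         seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    x <- stats::rnorm(n)
    z <- stats::rnorm(n)
    t_ev <- stats::rexp(n, base * exp(beta * x))
    ctime <- if (is.null(cens)) rep(Inf, n) else stats::rexp(n, cens)
    tibble::tibble(
      x = x, z = z,
      time = pmin(t_ev, ctime, 30),
      event = as.integer(t_ev <= pmin(ctime, 30)))
  })
}

# Reduced-size simulation configs used across tests (fewer species so the
# suite stays fast; the species count never enters the property checked).
small_config <- function(n_families = 10, n_unrelated = 300,
                         n_lipid_species = 15, ...) {
  sim_config(n_families = n_families, n_unrelated = n_unrelated,
             n_lipid_species = n_lipid_species, ...)
}

# O(m^2) definitional Benjamini-Hochberg step-up oracle: with p sorted
# ascending, adj_(i) = min over j >= i of min(1, m * p_(j) / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m),
                function(i) min(1, min(m * ps[i:m] / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force path enumeration oracle: probability-weighted payoff sum
# over all root-to-leaf paths.
enumerate_paths <- function(node, prob = 1) {
  if (identical(node$type, "leaf")) {
    return(list(list(prob = prob,
                     payoff = c(cost = node$cost, qaly = node$qaly,
                                t2d = node$t2d))))
  }
  out <- list()
  for (b in node$branches) {
    out <- c(out, enumerate_paths(b$node, prob * b$prob))
  }
  out
}

enumeration_ev <- function(node) {
  paths <- enumerate_paths(node)
  Reduce(`+`, lapply(paths, function(p) p$prob * p$payoff))
}

random_tree <- function(depth, width = 3) {
  if (depth == 0 || runif(1) < 0.25) {
    return(list(type = "leaf", cost = runif(1, 0, 1000),
                qaly = runif(1, 3, 5), t2d = rbinom(1, 1, 0.3)))
  }
  k <- sample(2:width, 1)
  probs <- as.numeric(rmultinom(1, 100, rep(1, k))) / 100
  while (any(probs == 0)) {
    probs <- as.numeric(rmultinom(1, 100, rep(1, k))) / 100
  }
  list(type = "chance",
       branches = lapply(seq_len(k), function(i) {
         list(prob = probs[i], node = random_tree(depth - 1, width))
       }))
}
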