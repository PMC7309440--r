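# --- fixtures ---------------------------------------------------------------

# valid wide score table with optional dropout / missing-EEG / missing-feature
# groups (disjoint, in that order from the top)
make_scores <- function(n, seed = 1, n_dropout = 0, n_no_eeg = 0,
                        n_no_feat = 0) {
  stopifnot(n_dropout + n_no_eeg + n_no_feat <= n)
  set.seed(seed)
  items <- eegboost::hrsd_items()
  scores <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    treatment = sample(c("escitalopram", "sertraline", "venlafaxine_xr"),
                       n, replace = TRUE),
    eeg_present = TRUE, features_complete = TRUE)
  for (i in items$item) {
    b <- sample(0:items$scale_max[i], n, replace = TRUE)
    w <- pmax(b - sample(0:2, n, replace = TRUE), 0)
    scores[[sprintf("baseline_%02d", i)]] <- b
    scores[[sprintf("week8_%02d", i)]] <- w
  }
  if (n_dropout > 0) scores$week8_01[seq_len(n_dropout)] <- NA_integer_
  if (n_no_eeg > 0) {
    scores$eeg_present[n_dropout + seq_len(n_no_eeg)] <- FALSE
  }
  if (n_no_feat > 0) {
    scores$features_complete[n_dropout + n_no_eeg +
                               seq_len(n_no_feat)] <- FALSE
  }
  scores
}

# fabricated band-power table (no EEG synthesis): lognormal absolute powers,
# optionally with extra variance injected into one site/band so models have
# signal to find
fake_band_table <- function(n, seed = 1) {
  set.seed(seed)
  montage <- eegboost::eeg_montage()$site
  bands <- eegboost::eeg_bands()$band
  grid <- expand.grid(site = montage, band = bands,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(n), function(s) {
    absolute <- stats::rlnorm(nrow(grid), meanlog = rep(c(3, 2, 2.5, 1, 0),
                                                        each = 26) / 2,
                              sdlog = 0.5)
    tot <- tapply(absolute, grid$site, sum)
    tibble::tibble(subject_id = sprintf("S%04d", s), site = grid$site,
                   band = grid$band, absolute = absolute,
                   relative = absolute / tot[grid$site])
  })
  dplyr::bind_rows(rows)
}

# --- independent oracles ----------------------------------------------------

# exhaustive O(n^2) pair-counting concordance
c_index_oracle <- function(pred, y) {
  conc <- 0
  usable <- 0
  n <- length(y)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (y[i] == y[j]) next
      usable <- usable + 1
      dp <- pred[i] - pred[j]
      if (dp == 0) {
        conc <- conc + 0.5
      } else if (dp * (y[i] - y[j]) > 0) {
        conc <- conc + 1
      }
    }
  }
  conc / usable
}

# round doubles to the nearest single-precision value (tree evaluation in
# the boosting library happens in float32)
f32 <- function(v) readBin(writeBin(as.numeric(v), raw(), size = 4),
                           "numeric", size = 4, n = length(v))

# cover-weighted conditional expectation of one tree given the known set
tree_expectation <- function(nodes, node_id, x, known) {
  nd <- nodes[nodes$node_id == node_id, ]
  if (is.na(nd$feature)) return(nd$value)
  if (nd$feature %in% known) {
    child <- if (f32(x[[nd$feature]]) < f32(nd$split)) nd$yes else nd$no
    return(tree_expectation(nodes, child, x, known))
  }
  cy <- nodes$cover[nodes$node_id == nd$yes]
  cn <- nodes$cover[nodes$node_id == nd$no]
  (cy * tree_expectation(nodes, nd$yes, x, known) +
     cn * tree_expectation(nodes, nd$no, x, known)) / (cy + cn)
}

# brute-force Shapley by exhaustive subset enumeration over the parsed trees
# (tree-conditional expectation convention); returns list(phi, base_value)
shap_oracle <- function(trees, feats, base_score, X) {
  M <- length(feats)
  tree_ids <- unique(trees$tree)
  node_sets <- lapply(tree_ids, function(t) trees[trees$tree == t, ])
  value_fn <- function(x, known) {
    base_score + sum(vapply(node_sets, function(nodes) {
      tree_expectation(nodes, nodes$node_id[1], x, known)
    }, numeric(1)))
  }
  fact <- factorial(0:M)
  phi <- matrix(0, nrow(X), M, dimnames = list(NULL, feats))
  base_value <- numeric(nrow(X))
  for (r in seq_len(nrow(X))) {
    x <- as.list(stats::setNames(as.numeric(X[r, ]), colnames(X)))
    vals <- vapply(0:(2^M - 1), function(mask) {
      value_fn(x, feats[bitwAnd(mask, 2^(0:(M - 1))) > 0])
    }, numeric(1))
    base_value[r] <- vals[1]
    for (i in seq_len(M)) {
      for (mask in 0:(2^M - 1)) {
        if (bitwAnd(mask, 2^(i - 1)) > 0) next
        s <- sum(bitwAnd(mask, 2^(0:(M - 1))) > 0)
        wgt <- fact[s + 1] * fact[M - s] / fact[M + 1]
        phi[r, i] <- phi[r, i] +
          wgt * (vals[mask + 2^(i - 1) + 1] - vals[mask + 1])
      }
    }
  }
  list(phi = phi, base_value = base_value)
}

# numerical oracle for the univariate lasso objective: profile out the
# unpenalised intercept, then 1-D golden-section minimisation over the slope
lasso_oracle <- function(x, y, lambda) {
  obj <- function(b1) {
    b0 <- mean(y) - b1 * mean(x)
    mean((y - b0 - b1 * x)^2) / 2 + lambda * abs(b1)
  }
  opt <- stats::optimize(obj, interval = c(-1e3, 1e3), tol = 1e-10)
  b1 <- opt$minimum
  c(slope = b1, intercept = mean(y) - b1 * mean(x))
}

# pure-band amplitude profile over an arbitrary subset of sites
pure_profile <- function(band, amplitude, sites = c("O1", "Oz", "O2")) {
  prof <- matrix(0, length(sites), 5,
                 dimnames = list(sites, eegboost::eeg_bands()$band))
  prof[, band] <- amplitude
  prof
}
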