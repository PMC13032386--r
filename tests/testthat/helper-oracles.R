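# Independent oracles and fixture builders. Everything here is a deliberately
# naive reimplementation, kept free of the package's internal code paths.

# Step-up FDR adjustment written directly from the definition:
# q_(i) = min_{j>=i} min(1, p_(j) * m * cm / j), cm = 1 (BH) or sum(1/i) (BY).
naive_stepup <- function(p, cm) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, min(1, p[o[j]] * m * cm / j))
    q_sorted[i] <- best
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}
naive_bh <- function(p) naive_stepup(p, 1)
naive_by <- function(p) naive_stepup(p, sum(1 / seq_along(p)))

# Nested-loop Filter 1: blank a (protein, donor, subtype) replicate group
# when it holds fewer than min_detected detections.
brute_filter1 <- function(values, meta, min_detected = 2) {
  for (i in seq_len(nrow(values))) {
    for (d in unique(meta$donor_id)) {
      for (s in unique(meta$subtype[meta$donor_id == d])) {
        cols <- which(meta$donor_id == d & meta$subtype == s)
        ndet <- sum(!is.na(values[i, cols]))
        if (ndet > 0 && ndet < min_detected) values[i, cols] <- NA_real_
      }
    }
  }
  values
}

# Nested-loop Filter 2: blank a (protein, subtype) block when fewer than
# min_donors donors have any detection in it.
brute_filter2 <- function(values, meta, min_donors = 2) {
  for (i in seq_len(nrow(values))) {
    for (s in unique(meta$subtype)) {
      cols <- which(meta$subtype == s)
      donors <- unique(meta$donor_id[cols])
      ndon <- 0
      for (d in donors) {
        dc <- cols[meta$donor_id[cols] == d]
        if (any(!is.na(values[i, dc]))) ndon <- ndon + 1
      }
      if (ndon > 0 && ndon < min_donors) values[i, cols] <- NA_real_
    }
  }
  values
}

# Maximum-likelihood fit of a left-censored normal: k values censored below
# the known threshold, the rest observed.
mle_censored_normal <- function(obs, n_censored, threshold) {
  nll <- function(par) {
    if (par[2] <= 0) return(1e10)
    -(sum(stats::dnorm(obs, par[1], par[2], log = TRUE)) +
        n_censored * stats::pnorm(threshold, par[1], par[2], log.p = TRUE))
  }
  fit <- stats::optim(c(mean(obs), stats::sd(obs)), nll)
  c(mu = fit$par[1], sigma = fit$par[2])
}

# Exclusive Venn regions by per-element membership enumeration.
brute_venn <- function(sets) {
  universe <- unique(unlist(sets))
  out <- list()
  for (el in universe) {
    key <- paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
                 collapse = "&")
    out[[key]] <- c(out[[key]], el)
  }
  out
}

# Small random design fixture: intensity table + metadata with an
# MCAR detection mask (for filter and set-algebra property tests).
make_fixture <- function(n_proteins = 50, donors = 3, subtypes = c("A", "B", "C"),
                         replicates = 3, p_detect = 0.6, seed = 1,
                         conditions = "IBM") {
  set.seed(seed)
  rows <- expand.grid(replicate_index = seq_len(replicates),
                      subtype = subtypes,
                      donor_id = paste0("D", seq_len(donors)),
                      stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = paste(rows$donor_id, rows$subtype,
                                       rows$replicate_index, sep = "_"),
                     donor_id = rows$donor_id, condition = conditions,
                     subtype = rows$subtype,
                     replicate_index = rows$replicate_index,
                     stringsAsFactors = FALSE)
  vals <- matrix(2^stats::rnorm(n_proteins * nrow(meta), 20, 2),
                 n_proteins, nrow(meta),
                 dimnames = list(sprintf("P%03d", seq_len(n_proteins)),
                                 meta$sample_id))
  vals[matrix(stats::runif(length(vals)) > p_detect, nrow(vals))] <- NA_real_
  list(table = intensity_table(vals), meta = meta)
}

# Random gene symbols for set-algebra fixtures.
random_genes <- function(n, pool = 40) {
  sample(sprintf("G%02d", seq_len(pool)), n, replace = FALSE)
}
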