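#' Simulation configuration
#'
#' Defines a synthetic LCM-MS study: the donor/subtype/replicate design,
#' the log-normal abundance model and the intensity-dependent detection
#' model. The default design mirrors a myofiber study with three disease
#' donors, three pathology-associated fiber subtypes and two control
#' donors contributing large and small fibers, all in triplicate.
#'
#' Intensities are generated additively on the log2 scale,
#' \deqn{x_{ij} = b_i + \delta_i \cdot [\mathrm{disease}] + d_{i,k(j)} + e_{ij},}
#' with protein baseline \eqn{b_i \sim N(\mu_0, \sigma_0^2)}, condition
#' effect \eqn{\delta_i} (\eqn{\pm}\code{de_effect} for a fraction
#' \code{frac_de} of proteins), donor effect \eqn{d_{i,k}} and replicate
#' noise \eqn{e_{ij}}, then exported on the raw scale as \eqn{2^{x}}.
#' Each cell is detected with probability
#' \eqn{\mathrm{logit}^{-1}(\alpha + \beta x_{ij})}, so missingness is
#' left-censored: detection rises with abundance. A fraction
#' \code{frac_subtype_unique} of proteins is structurally absent from a
#' random strict subset of the disease subtypes.
#'
#' @param n_proteins number of non-contaminant protein groups
#' @param conditions named list, one entry per condition, each a list with
#'   \code{donors} (count) and \code{subtypes} (character vector)
#' @param disease_condition name of the condition carrying the condition
#'   effect and the subtype-restricted proteins
#' @param replicates replicates per donor x subtype (default 3)
#' @param baseline_mean,baseline_sd mean and between-protein SD of the
#'   log2 baseline abundance (defaults 22, 3)
#' @param donor_sd SD of the per-donor, per-protein effect (log2 units,
#'   default 0.3)
#' @param replicate_sd SD of replicate noise (log2 units, default 0.5)
#' @param frac_de fraction of proteins with a condition effect (default 0.1)
#' @param de_effect absolute condition effect in log2 units (default 1.5);
#'   sign is drawn at random per protein
#' @param frac_subtype_unique fraction of proteins truly expressed in only
#'   a strict subset of the disease subtypes (default 0.1)
#' @param missing_intercept,missing_slope logistic detection-model
#'   coefficients on log2 intensity. The defaults (-42.5 and 2.5, i.e. a
#'   detection midpoint at log2 intensity 17, about 1.7 SD below the
#'   median abundance) emulate a filtered protein-group matrix:
#'   detection is essentially complete above the median abundance and
#'   falls steeply over the lowest-abundance quintile, giving roughly
#'   90\% overall completeness
#' @param n_contaminants rows added with a \code{"contam sp|"} accession
#'   prefix (default 0)
#' @param low_depth_sample optional sample id whose detection probability
#'   is multiplied by \code{low_depth_factor}
#' @param low_depth_factor multiplier in (0,1) applied to the detection
#'   probability of \code{low_depth_sample} (default 0.3)
#' @param seed integer seed; identical configs give bit-identical datasets
#' @return an object of class \code{sim_config}
#' @export
sim_config <- function(n_proteins = 2000,
                       conditions = list(
                         IBM = list(donors = 3,
                                    subtypes = c("eMyH-F", "CN-F", "Inf-F")),
                         control = list(donors = 2,
                                        subtypes = c("control-large",
                                                     "control-small"))),
                       disease_condition = "IBM",
                       replicates = 3,
                       baseline_mean = 22, baseline_sd = 3,
                       donor_sd = 0.3, replicate_sd = 0.5,
                       frac_de = 0.1, de_effect = 1.5,
                       frac_subtype_unique = 0.1,
                       missing_intercept = -42.5, missing_slope = 2.5,
                       n_contaminants = 0,
                       low_depth_sample = NULL, low_depth_factor = 0.3,
                       seed = 1) {
  cfg <- list(n_proteins = as.integer(n_proteins), conditions = conditions,
              disease_condition = disease_condition,
              replicates = as.integer(replicates),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              donor_sd = donor_sd, replicate_sd = replicate_sd,
              frac_de = frac_de, de_effect = de_effect,
              frac_subtype_unique = frac_subtype_unique,
              missing_intercept = missing_intercept,
              missing_slope = missing_slope,
              n_contaminants = as.integer(n_contaminants),
              low_depth_sample = low_depth_sample,
              low_depth_factor = low_depth_factor,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_proteins < 1L) stop("n_proteins must be positive")
  if (cfg$replicates < 1L) stop("replicates must be >= 1")
  if (!cfg$disease_condition %in% names(cfg$conditions))
    stop("disease_condition must name an entry of 'conditions'")
  for (cn in names(cfg$conditions)) {
    cc <- cfg$conditions[[cn]]
    if (cc$donors < 1L) stop("condition '", cn, "' must have >= 1 donor")
    if (length(cc$subtypes) < 1L) stop("condition '", cn, "' needs subtypes")
  }
  fr <- c(cfg$frac_de, cfg$frac_subtype_unique)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  sds <- c(cfg$baseline_sd, cfg$donor_sd, cfg$replicate_sd)
  if (any(sds < 0)) stop("sd parameters must be >= 0")
  if (cfg$missing_slope < 0)
    stop("missing_slope must be >= 0 (detection non-decreasing in intensity)")
  if (cfg$n_contaminants < 0) stop("n_contaminants must be >= 0")
  if (!is.null(cfg$low_depth_sample) &&
      (cfg$low_depth_factor <= 0 || cfg$low_depth_factor >= 1))
    stop("low_depth_factor must lie in (0, 1)")
  invisible(cfg)
}

## sample frame of a design: one row per (condition, donor, subtype, replicate)
sim_sample_frame <- function(cfg) {
  rows <- list()
  for (cn in names(cfg$conditions)) {
    cc <- cfg$conditions[[cn]]
    for (d in seq_len(cc$donors)) {
      donor <- paste0(cn, d)
      for (s in cc$subtypes) {
        for (r in seq_len(cfg$replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = paste(donor, s, r, sep = "_"),
            donor_id = donor, condition = cn, subtype = s,
            replicate_index = r, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a synthetic LCM-MS dataset
#'
#' Generates a raw-scale protein-group intensity matrix with
#' intensity-dependent missingness, the matching sample metadata, and a
#' ground-truth table recording each protein's baseline, condition effect,
#' subtype presence pattern and contaminant status.
#'
#' @param config a [sim_config()]
#' @return a list of class \code{fiber_sim} with elements
#'   \describe{
#'     \item{table}{an [intensity_table()] (raw scale, \code{NA} = not
#'       detected), contaminant rows included}
#'     \item{meta}{sample metadata data.frame}
#'     \item{truth}{list with \code{proteins} (per-protein truth
#'       data.frame), \code{samples} (per-sample depth factors) and
#'       \code{params} (the detection-model coefficients used)}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 100, seed = 42))
#' sim$table
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  meta <- sim_sample_frame(cfg)
  n_samp <- nrow(meta)
  np <- cfg$n_proteins
  dz <- cfg$disease_condition
  dz_subtypes <- cfg$conditions[[dz]]$subtypes

  prot_id <- sprintf("P%05d", seq_len(np))
  gene <- sprintf("GENE%d", seq_len(np))

  baseline <- stats::rnorm(np, cfg$baseline_mean, cfg$baseline_sd)

  ## disjoint DE and subtype-restricted index sets keep the truth unambiguous
  n_de <- round(cfg$frac_de * np)
  n_uni <- round(cfg$frac_subtype_unique * np)
  if (n_de + n_uni > np) stop("frac_de + frac_subtype_unique exceed 1")
  pick <- sample.int(np, n_de + n_uni)
  idx_de <- pick[seq_len(n_de)]
  idx_uni <- pick[n_de + seq_len(n_uni)]

  cond_effect <- numeric(np)
  if (n_de > 0)
    cond_effect[idx_de] <- cfg$de_effect * sample(c(-1, 1), n_de, replace = TRUE)

  ## presence pattern over disease subtypes: strict non-empty subsets
  pattern <- rep("all", np)
  if (n_uni > 0 && length(dz_subtypes) > 1) {
    subsets <- list()
    for (k in seq_len(length(dz_subtypes) - 1L))
      subsets <- c(subsets, utils::combn(dz_subtypes, k, simplify = FALSE))
    pattern[idx_uni] <- vapply(sample.int(length(subsets), n_uni, replace = TRUE),
                               function(i) paste(subsets[[i]], collapse = "|"),
                               character(1))
  }

  donors <- unique(meta$donor_id)
  donor_eff <- matrix(stats::rnorm(np * length(donors), 0, cfg$donor_sd),
                      np, length(donors), dimnames = list(NULL, donors))

  is_disease <- meta$condition == dz
  x <- matrix(baseline, np, n_samp) +
    outer(cond_effect, as.numeric(is_disease)) +
    donor_eff[, match(meta$donor_id, donors), drop = FALSE] +
    matrix(stats::rnorm(np * n_samp, 0, cfg$replicate_sd), np, n_samp)

  ## contaminant rows: same abundance model, no effects, always expressed
  nc <- cfg$n_contaminants
  if (nc > 0) {
    cb <- stats::rnorm(nc, cfg$baseline_mean, cfg$baseline_sd)
    xc <- matrix(cb, nc, n_samp) +
      matrix(stats::rnorm(nc * n_samp, 0, cfg$replicate_sd), nc, n_samp)
    x <- rbind(x, xc)
    prot_id <- c(prot_id, sprintf("contam sp|CONT%d", seq_len(nc)))
    gene <- c(gene, sprintf("CONT%d", seq_len(nc)))
    baseline <- c(baseline, cb)
    cond_effect <- c(cond_effect, numeric(nc))
    pattern <- c(pattern, rep("all", nc))
  }
  ntot <- np + nc

  depth <- rep(1, n_samp)
  if (!is.null(cfg$low_depth_sample)) {
    j <- match(cfg$low_depth_sample, meta$sample_id)
    if (is.na(j)) stop("low_depth_sample '", cfg$low_depth_sample,
                       "' not in the design")
    depth[j] <- cfg$low_depth_factor
  }

  p_det <- stats::plogis(cfg$missing_intercept + cfg$missing_slope * x)
  p_det <- sweep(p_det, 2, depth, `*`)
  detected <- matrix(stats::runif(ntot * n_samp), ntot, n_samp) < p_det

  ## structural absence outside the truth presence pattern
  restricted <- pattern != "all"
  if (any(restricted)) {
    for (s in dz_subtypes) {
      cols <- which(is_disease & meta$subtype == s)
      absent <- restricted &
        !vapply(strsplit(pattern, "|", fixed = TRUE),
                function(p) s %in% p, logical(1))
      detected[absent, cols] <- FALSE
    }
  }

  vals <- 2^x
  vals[!detected] <- NA_real_
  dimnames(vals) <- list(prot_id, meta$sample_id)

  truth_prot <- data.frame(protein_id = prot_id, gene = gene,
                           baseline = baseline, condition_effect = cond_effect,
                           pattern = pattern,
                           is_contaminant = startsWith(prot_id, "contam"),
                           stringsAsFactors = FALSE)
  structure(list(table = intensity_table(vals, gene, scale = "raw"),
                 meta = meta,
                 truth = list(proteins = truth_prot,
                              samples = data.frame(sample_id = meta$sample_id,
                                                   depth_factor = depth,
                                                   stringsAsFactors = FALSE),
                              params = list(
                                missing_intercept = cfg$missing_intercept,
                                missing_slope = cfg$missing_slope)),
                 config = cfg),
            class = "fiber_sim")
}

#' @export
print.fiber_sim <- function(x, ...) {
  cat("fiber_sim dataset\n")
  print(x$table)
  cat(sprintf("  samples: %d (%s)\n", nrow(x$meta),
              paste(sprintf("%s: %d", names(table(x$meta$condition)),
                            table(x$meta$condition)), collapse = ", ")))
  invisible(x)
}

#' Simulate a left-censored normal column
#'
#' Draws \code{n} normal values and censors the lowest
#' \code{floor(censor_quantile * n)} of them (set to \code{NA}), emulating
#' a detection limit. Used as a fixture with known truth for the QRILC
#' estimator.
#'
#' @param n number of draws (>= 10)
#' @param mean,sd normal parameters (log2-intensity units)
#' @param censor_quantile fraction in (0,1) of values to censor from the left
#' @param seed integer seed
#' @return a list with \code{x} (vector with \code{NA} where censored),
#'   \code{mean}, \code{sd}, \code{threshold} (largest censored value;
#'   \code{-Inf} when nothing was censored), \code{n_censored}, and
#'   \code{complete} (the uncensored draws, for oracle comparisons).
#' @export
simulate_censored_column <- function(n, mean = 20, sd = 2,
                                     censor_quantile = 0.2, seed = 1) {
  if (n < 10) stop("n must be >= 10 for a meaningful censored fit")
  if (censor_quantile <= 0 || censor_quantile >= 1)
    stop("censor_quantile must lie in (0, 1)")
  if (sd <= 0) stop("sd must be > 0")
  set.seed(seed)
  full <- stats::rnorm(n, mean, sd)
  k <- floor(censor_quantile * n)
  x <- full
  threshold <- -Inf
  if (k > 0) {
    ord <- order(full)
    x[ord[seq_len(k)]] <- NA_real_
    threshold <- full[ord[k]]
  }
  list(x = x, mean = mean, sd = sd, threshold = threshold,
       n_censored = k, complete = full)
}
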