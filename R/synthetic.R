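#' Configuration for a synthetic toxicity cohort
#'
#' Defines the shape and signal structure of a simulated acute-toxicity
#' dataset: a compound panel with binary fingerprints, numeric chemical
#' descriptors, qHTS cell-viability dose-response profiles, pLD50 values
#' (-log10 mol/kg), and a bioactivity training table for the multi-target
#' scorer.  The defaults emulate the published study cohort: 367 compounds
#' with a 275:92 nontoxic:toxic imbalance, 192 chemical descriptors,
#' 477 protein targets, and 13 cell lines assayed at 14 concentrations
#' between 0.6 and 92 uM.
#'
#' Toxicity signal originates in a small set of latent mechanisms whose
#' activations drive, in parallel, (i) pLD50 through
#' \code{domain_signal_weights}, (ii) mechanism-linked fingerprint bits,
#' (iii) chemical descriptors (linear mixtures of the chemical-facing
#' mechanisms), (iv) qHTS potency (cytotox-facing mechanisms lower the Hill
#' EC50), and (v) target-bioactivity labels (target-facing mechanisms).
#' Splitting the signal across domains in this way rewards descriptor
#' integration, the property the modelling study is designed to measure.
#'
#' @param n_compounds number of cohort compounds.
#' @param n_toxic expected number of toxic compounds (pLD50 > 3).
#' @param n_chem_descriptors number of numeric chemical descriptors.
#' @param n_fingerprint_bits size of the binary fingerprint universe.
#' @param n_targets number of protein targets in the bioactivity table.
#' @param n_cell_lines,n_concentrations qHTS panel dimensions.
#' @param concentration_range assay concentration range in uM (low, high).
#' @param n_latent_mechanisms number of latent toxicity mechanisms; assigned
#'   round-robin to the chemical, target and cytotox domains.
#' @param n_nuisance_mechanisms number of toxicity-irrelevant latent
#'   factors (protein-family-like structure).  They shape fingerprints
#'   and decoy-target bioactivity, giving decoy target scores the same
#'   kind of correlation structure as mechanism-linked ones, but never
#'   enter pLD50.
#' @param n_clusters number of scaffold clusters.  Compounds are assigned
#'   to clusters with Zipf-like frequencies; each cluster carries a large
#'   toxicity-irrelevant offset in chemical-descriptor space plus a
#'   cluster-level toxicity effect.  Rare-cluster compounds are therefore
#'   chemically novel relative to any training split and harder to
#'   classify -- the structure behind applicability-domain decay.
#' @param cluster_offset_sd standard deviation of the per-cluster chemical
#'   descriptor offsets (default 0.8; a major component of
#'   chemical-space distances).
#' @param cluster_effect_share fraction of the chemical-domain toxicity
#'   signal carried by the scaffold-cluster effect rather than by
#'   mechanism activations, in [0, 1).  The cluster effect cannot be
#'   learned for scaffolds absent from a training split, which is what
#'   makes accuracy fall with chemical novelty.
#' @param domain_signal_weights named fractions (chemical, target, cytotox)
#'   of toxicity signal carried by each domain; must sum to 1.  The
#'   default puts the largest share on the chemical domain, matching the
#'   published regime in which the chemical-only model is the strongest
#'   single-domain classifier.
#' @param noise_sd standard deviation of the Gaussian pLD50 noise; qHTS
#'   response noise uses \code{noise_sd / 6} (response scale is 0-1).
#' @param hill_emax_range,hill_ec50_range,hill_slope_range positive intervals
#'   for the per-curve Hill parameters (EC50 in uM).
#' @param n_bioactivity_compounds size of the separate compound pool used to
#'   train the target scorer.
#' @param records_per_target bioactivity records drawn per target, capped
#'   at the pool size (>= 50 so every target survives the scorer's
#'   record-count filter).  The default equals the pool size: every target
#'   is assayed against every pool compound, which keeps the scorer's
#'   pool-wide feature counts commensurate with its per-target active
#'   counts.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return An object of class \code{synth_config}.
#' @seealso [generate_cohort()]
#' @export
synth_config <- function(n_compounds = 367L,
                         n_toxic = 92L,
                         n_chem_descriptors = 192L,
                         n_fingerprint_bits = 1024L,
                         n_targets = 477L,
                         n_cell_lines = 13L,
                         n_concentrations = 14L,
                         concentration_range = c(0.6, 92),
                         n_latent_mechanisms = 12L,
                         n_nuisance_mechanisms = 12L,
                         n_clusters = 12L,
                         cluster_offset_sd = 0.8,
                         cluster_effect_share = 0.3,
                         domain_signal_weights = c(chemical = 0.45,
                                                   target = 0.275,
                                                   cytotox = 0.275),
                         noise_sd = 0.3,
                         hill_emax_range = c(0.7, 1.0),
                         hill_ec50_range = c(1, 60),
                         hill_slope_range = c(0.8, 2.5),
                         n_bioactivity_compounds = 600L,
                         records_per_target = n_bioactivity_compounds,
                         seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_toxic = as.integer(n_toxic),
              n_chem_descriptors = as.integer(n_chem_descriptors),
              n_fingerprint_bits = as.integer(n_fingerprint_bits),
              n_targets = as.integer(n_targets),
              n_cell_lines = as.integer(n_cell_lines),
              n_concentrations = as.integer(n_concentrations),
              concentration_range = as.numeric(concentration_range),
              n_latent_mechanisms = as.integer(n_latent_mechanisms),
              n_nuisance_mechanisms = as.integer(n_nuisance_mechanisms),
              n_clusters = as.integer(n_clusters),
              cluster_offset_sd = as.numeric(cluster_offset_sd),
              cluster_effect_share = as.numeric(cluster_effect_share),
              domain_signal_weights = domain_signal_weights,
              noise_sd = as.numeric(noise_sd),
              hill_emax_range = as.numeric(hill_emax_range),
              hill_ec50_range = as.numeric(hill_ec50_range),
              hill_slope_range = as.numeric(hill_slope_range),
              n_bioactivity_compounds = as.integer(n_bioactivity_compounds),
              records_per_target = as.integer(records_per_target),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c("n_compounds", "n_toxic", "n_chem_descriptors",
              "n_fingerprint_bits", "n_targets", "n_cell_lines",
              "n_concentrations", "n_latent_mechanisms", "n_clusters",
              "n_bioactivity_compounds", "records_per_target")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("synth_config: '", nm, "' must be a positive count", call. = FALSE)
  }
  if (cfg$n_toxic >= cfg$n_compounds)
    stop("synth_config: n_toxic must be smaller than n_compounds",
         call. = FALSE)
  if (length(cfg$n_nuisance_mechanisms) != 1L ||
      is.na(cfg$n_nuisance_mechanisms) || cfg$n_nuisance_mechanisms < 0L)
    stop("synth_config: 'n_nuisance_mechanisms' must be a nonnegative ",
         "count", call. = FALSE)
  w <- cfg$domain_signal_weights
  if (length(w) != 3L || is.null(names(w)) ||
      !setequal(names(w), c("chemical", "target", "cytotox")))
    stop("synth_config: domain_signal_weights must be named ",
         "(chemical, target, cytotox)", call. = FALSE)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("synth_config: domain_signal_weights must be nonnegative and sum ",
         "to 1", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("synth_config: noise_sd must be nonnegative", call. = FALSE)
  if (cfg$cluster_effect_share < 0 || cfg$cluster_effect_share >= 1)
    stop("synth_config: cluster_effect_share must be in [0, 1)",
         call. = FALSE)
  for (nm in c("hill_emax_range", "hill_ec50_range", "hill_slope_range",
               "concentration_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      stop("synth_config: '", nm, "' must be a positive interval (low, high)",
           call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d compounds (%d toxic expected), seed %d\n",
              x$n_compounds, x$n_toxic, x$seed))
  cat(sprintf("  %d chemical descriptors, %d targets, %d cell lines x %d concentrations\n",
              x$n_chem_descriptors, x$n_targets, x$n_cell_lines,
              x$n_concentrations))
  cat(sprintf("  domain signal weights: chemical %.2f, target %.2f, cytotox %.2f\n",
              x$domain_signal_weights[["chemical"]],
              x$domain_signal_weights[["target"]],
              x$domain_signal_weights[["cytotox"]]))
  invisible(x)
}

# facing assignment of latent mechanisms: toxicity mechanisms round-robin
# over the three domains, then the toxicity-irrelevant nuisance factors
mechanism_facing <- function(k, k_nuisance = 0L) {
  c(rep(c("chemical", "target", "cytotox"), length.out = k),
    rep("nuisance", k_nuisance))
}

# shared log-spaced concentration grid in uM
concentration_grid <- function(cfg) {
  exp(seq(log(cfg$concentration_range[1]), log(cfg$concentration_range[2]),
          length.out = cfg$n_concentrations))
}

#' Noise-free Hill dose-response curve
#'
#' \code{emax * conc^slope / (ec50^slope + conc^slope)}; the fractional
#' loss of cell viability at each assay concentration.
#'
#' @param conc concentrations (uM).
#' @param emax maximal response.
#' @param ec50 half-maximal concentration (uM).
#' @param slope Hill coefficient.
#' @return numeric vector of responses, nondecreasing in \code{conc}.
#' @export
hill_response <- function(conc, emax, ec50, slope) {
  emax * conc^slope / (ec50^slope + conc^slope)
}

# draw fingerprints for a matrix of mechanism activations:
# mechanism-linked bits switch on with probability increasing in activation,
# all other bits at a low background rate.  Never returns an empty set.
draw_fingerprints <- function(M, fp_bits, n_bits, ids, background = 0.02) {
  n <- nrow(M)
  k <- ncol(M)
  fps <- vector("list", n)
  for (i in seq_len(n)) {
    on <- which(stats::runif(n_bits) < background)
    for (m in seq_len(k)) {
      bits <- fp_bits[[m]]
      p_on <- stats::plogis(-2.5 + 2.2 * M[i, m])
      on <- c(on, bits[stats::runif(length(bits)) < p_on])
    }
    on <- sort(unique(as.integer(on)))
    if (length(on) == 0L) on <- 1L    # fingerprints must be non-empty
    fps[[i]] <- on
  }
  names(fps) <- ids
  fps
}

#' Generate a synthetic triply-heterogeneous toxicity cohort
#'
#' Draws a full simulated dataset according to a [synth_config()]: latent
#' mechanism activations, pLD50 values thresholdable into the published
#' 275:92 class balance, fingerprints, chemical descriptors, qHTS
#' dose-response profiles, and a bioactivity table for training the target
#' scorer.  pLD50 noise is resampled (up to 100 attempts) until the
#' thresholded toxic and nontoxic counts both land within 15% of the
#' configured counts; otherwise generation fails naming the constraint.
#'
#' The latent ground truth (mechanism activations, facing assignment,
#' mechanism-linked fingerprint bits and target links) is stored under
#' \code{$truth} for recovery tests only; no modelling function reads it.
#'
#' @param config a [synth_config()].
#' @return An object of class \code{tox_cohort}: a list with elements
#'   \code{compound_ids}, \code{fingerprints} (named list of sorted integer
#'   bit sets), \code{chem_descriptors} (matrix), \code{qhts} (long
#'   data.frame: compound_id, cell_line, concentration_uM, response),
#'   \code{pld50} (named numeric), \code{bioactivity} (data.frame:
#'   compound_id, target_id, active), \code{bio_fingerprints},
#'   \code{config}, and \code{truth}.
#' @examples
#' cohort <- generate_cohort(synth_config(n_compounds = 60, n_toxic = 15,
#'   n_chem_descriptors = 12, n_fingerprint_bits = 128, n_targets = 8,
#'   n_cell_lines = 3, n_bioactivity_compounds = 80, seed = 7))
#' table(classify_toxicity(cohort$pld50))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(config$seed)

  n <- config$n_compounds
  k <- config$n_latent_mechanisms
  k_all <- k + config$n_nuisance_mechanisms
  facing <- mechanism_facing(k, config$n_nuisance_mechanisms)
  ids <- sprintf("CPD%05d", seq_len(n))

  # (1) latent activations (toxicity mechanisms + nuisance factors):
  # half-normal, independent
  M <- matrix(abs(stats::rnorm(n * k_all)), n, k_all,
              dimnames = list(ids, sprintf("%s_%d", facing,
                                           seq_len(k_all))))

  # (2) scaffold clusters: Zipf-like sizes, a toxicity effect per cluster
  cluster <- sample.int(config$n_clusters, n, replace = TRUE,
                        prob = 1 / seq_len(config$n_clusters))
  gamma <- stats::rnorm(config$n_clusters)

  # (3) toxicity propensity: per-domain standardized mean activation,
  # weighted by domain_signal_weights.  The chemical share is split
  # equally between mechanism activations and the scaffold-cluster
  # effect, both of which are visible only through chemical descriptors.
  w <- config$domain_signal_weights
  dom_score <- function(d) {
    cols <- which(facing == d)
    if (length(cols) == 0L) return(rep(0, n))
    v <- rowMeans(M[, cols, drop = FALSE])
    as.numeric(scale(v))
  }
  g <- gamma[cluster]
  z_gamma <- if (stats::sd(g) > 0) as.numeric(scale(g)) else rep(0, n)
  es <- config$cluster_effect_share
  z_chem <- sqrt(1 - es) * dom_score("chemical") + sqrt(es) * z_gamma
  s <- w[["chemical"]] * z_chem +
       w[["target"]]   * dom_score("target") +
       w[["cytotox"]]  * dom_score("cytotox")
  if (stats::sd(s) == 0) s <- stats::rnorm(n)   # all-zero-weight degenerate
  p_tox <- config$n_toxic / n
  cut <- stats::quantile(s, 1 - p_tox, names = FALSE, type = 7)
  # bimodal base: propensity above the cut maps above the toxic threshold,
  # below the cut maps below the nontoxic threshold, leaving a gap so that
  # only noise places compounds in the discarded marginal band (2, 3)
  base <- ifelse(s >= cut, 3.3 + 0.9 * (s - cut), 1.7 - 0.9 * (cut - s))
  n_nontox <- n - config$n_toxic
  ok <- FALSE
  for (attempt in seq_len(100L)) {
    pld50 <- base + stats::rnorm(n, 0, config$noise_sd)
    nt <- sum(pld50 > 3)
    nn <- sum(pld50 < 2)
    if (abs(nt - config$n_toxic) <= 0.15 * config$n_toxic &&
        abs(nn - n_nontox) <= 0.15 * n_nontox) {
      ok <- TRUE
      break
    }
  }
  if (!ok)
    stop("generate_cohort: could not reach toxic/nontoxic class counts ",
         "within 15% of (", config$n_toxic, ", ", n_nontox,
         ") after 100 pLD50 noise resamples", call. = FALSE)
  names(pld50) <- ids

  # (3) fingerprints: each latent factor owns a small block of linked bits
  bits_per_mech <- max(8L, min(12L,
                               config$n_fingerprint_bits %/% (2L * k_all)))
  # never allocate more linked bits than the universe holds
  bits_per_mech <- max(1L, min(bits_per_mech,
                               config$n_fingerprint_bits %/% k_all))
  all_bits <- sample.int(config$n_fingerprint_bits, bits_per_mech * k_all)
  fp_bits <- lapply(split(all_bits,
                          rep(seq_len(k_all), each = bits_per_mech)),
                    sort)
  fingerprints <- draw_fingerprints(M, fp_bits, config$n_fingerprint_bits, ids)

  # (4) chemical descriptors: each descriptor reads out mainly one
  # chemical-facing mechanism (descriptors measure specific structural
  # properties), plus scaffold-cluster offsets, so cluster identity (and
  # with it the cluster toxicity effect) is encoded in, and only in, the
  # chemical block
  chem_mech <- which(facing == "chemical")
  W <- matrix(0, length(chem_mech), config$n_chem_descriptors)
  primary <- rep(seq_along(chem_mech),
                 length.out = config$n_chem_descriptors)
  for (j in seq_len(config$n_chem_descriptors))
    W[primary[j], j] <- sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.2)
  offsets <- matrix(stats::rnorm(config$n_clusters *
                                   config$n_chem_descriptors, 0,
                                 config$cluster_offset_sd),
                    config$n_clusters, config$n_chem_descriptors)
  chem <- M[, chem_mech, drop = FALSE] %*% W +
    offsets[cluster, , drop = FALSE] +
    matrix(stats::rnorm(n * config$n_chem_descriptors, 0, 0.3), n)
  colnames(chem) <- sprintf("chem_%03d", seq_len(config$n_chem_descriptors))
  rownames(chem) <- ids

  # (5) qHTS: Hill curves.  A compound-level base potency is shared across
  # cell lines (with per-line jitter), and cytotox-facing activation lowers
  # the EC50 on the log2 scale, so the scaled dose-response block carries
  # the cytotox share of the toxicity signal.
  conc <- concentration_grid(config)
  cyto_mech <- which(facing == "cytotox")
  # potency shift scales with the summed activation, normalized by
  # sqrt(k) so its spread does not shrink as mechanisms are added
  a_cyto <- if (length(cyto_mech))
    rowSums(M[, cyto_mech, drop = FALSE]) / sqrt(length(cyto_mech))
  else rep(0, n)
  cells <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  resp_sd <- config$noise_sd / 6
  base_ec50 <- exp(stats::runif(n, log(config$hill_ec50_range[1]),
                                log(config$hill_ec50_range[2])))
  qhts <- vector("list", n * config$n_cell_lines)
  idx <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(config$n_cell_lines)) {
      emax <- stats::runif(1, config$hill_emax_range[1],
                           config$hill_emax_range[2])
      slope <- stats::runif(1, config$hill_slope_range[1],
                            config$hill_slope_range[2])
      ec50 <- base_ec50[i] * 2^(stats::rnorm(1, 0, 0.5) - 3 * a_cyto[i])
      resp <- hill_response(conc, emax, ec50, slope)
      if (resp_sd > 0)
        resp <- resp + stats::rnorm(length(conc), 0, resp_sd)
      qhts[[idx]] <- data.frame(compound_id = ids[i], cell_line = cells[j],
                                concentration_uM = conc, response = resp,
                                stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  qhts <- do.call(rbind, qhts)
  rownames(qhts) <- NULL

  # (6) bioactivity training pool for the target scorer
  nb <- config$n_bioactivity_compounds
  bio_ids <- sprintf("BIO%05d", seq_len(nb))
  Mb <- matrix(abs(stats::rnorm(nb * k_all)), nb, k_all,
               dimnames = list(bio_ids, colnames(M)))
  bio_fps <- draw_fingerprints(Mb, fp_bits, config$n_fingerprint_bits,
                               bio_ids)
  # a third of the targets link to target-facing mechanisms (a primary
  # mechanism, round-robin, blended with a random secondary one so
  # linked-target scores are not mutually redundant); the rest are
  # decoys.  Only the target-facing signal share can reach the
  # target-score descriptors.
  n_linked <- config$n_targets %/% 3L
  target_ids <- sprintf("T%04d", seq_len(config$n_targets))
  target_mech <- rep(NA_integer_, config$n_targets)
  tgt_mechs <- which(facing == "target")
  if (length(tgt_mechs) == 0L) tgt_mechs <- seq_len(k_all)
  nuis_mechs <- which(facing == "nuisance")
  if (length(nuis_mechs) == 0L) nuis_mechs <- tgt_mechs
  if (n_linked > 0L)
    target_mech[seq_len(n_linked)] <- rep(tgt_mechs, length.out = n_linked)
  # decoys are driven by nuisance factors with the same link form, so
  # their scores have comparable correlation structure
  decoy_mech <- sample(nuis_mechs, config$n_targets, replace = TRUE)
  primary_mech <- ifelse(is.na(target_mech), decoy_mech, target_mech)
  second_pool <- ifelse(is.na(target_mech),
                        sample(nuis_mechs, config$n_targets, replace = TRUE),
                        sample(tgt_mechs, config$n_targets, replace = TRUE))
  mix <- stats::runif(config$n_targets, 0.6, 1.0)
  m_rec <- min(config$records_per_target, nb)
  rec_cpd <- character(0); rec_tgt <- character(0); rec_act <- integer(0)
  for (t in seq_len(config$n_targets)) {
    cpds <- sample.int(nb, m_rec)
    p_act <- stats::plogis(-1.0 + 1.1 * (mix[t] * Mb[cpds, primary_mech[t]] +
                             (1 - mix[t]) * Mb[cpds, second_pool[t]]))
    act <- as.integer(stats::runif(m_rec) < p_act)
    rec_cpd <- c(rec_cpd, bio_ids[cpds])
    rec_tgt <- c(rec_tgt, rep(target_ids[t], m_rec))
    rec_act <- c(rec_act, act)
  }
  bioactivity <- data.frame(compound_id = rec_cpd, target_id = rec_tgt,
                            active = rec_act, stringsAsFactors = FALSE)

  structure(list(compound_ids = ids,
                 fingerprints = fingerprints,
                 chem_descriptors = chem,
                 qhts = qhts,
                 pld50 = pld50,
                 bioactivity = bioactivity,
                 bio_fingerprints = bio_fps,
                 config = config,
                 truth = list(mechanisms = M,
                              facing = facing,
                              fp_bits = fp_bits,
                              target_mech = stats::setNames(target_mech,
                                                            target_ids),
                              bio_mechanisms = Mb,
                              cluster = stats::setNames(cluster, ids),
                              cluster_effect = gamma)),
            class = "tox_cohort")
}

#' @export
print.tox_cohort <- function(x, ...) {
  cls <- classify_toxicity(x$pld50)
  cat("Synthetic toxicity cohort\n")
  cat(sprintf("  %d compounds: %d toxic, %d nontoxic, %d marginal\n",
              length(x$compound_ids), sum(cls == "toxic"),
              sum(cls == "nontoxic"), sum(cls == "marginal")))
  cat(sprintf("  %d chemical descriptors; qHTS: %d cell lines x %d concentrations\n",
              ncol(x$chem_descriptors), x$config$n_cell_lines,
              x$config$n_concentrations))
  cat(sprintf("  bioactivity table: %d records over %d targets\n",
              nrow(x$bioactivity), length(unique(x$bioactivity$target_id))))
  invisible(x)
}

## ---- cohort serialization: one human-readable CSV per table ----

# numeric columns round-trip doubles exactly through "%.17g"
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE,
                       check.names = FALSE, optional = TRUE)
  if (nrow(df) == 0L) {   # preserve headers for empty tables
    out <- df[0, , drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

fingerprints_to_df <- function(fps, idcol = "compound_id") {
  df <- data.frame(id = as.character(names(fps)),
                   bits = vapply(fps, function(b) paste(b, collapse = " "),
                                 "", USE.NAMES = FALSE),
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df)[1] <- idcol
  df
}

matrix_to_df <- function(m, idcol = "compound_id") {
  ids <- rownames(m)
  if (is.null(ids)) ids <- character(nrow(m))
  df <- data.frame(id = ids, as.data.frame(m, optional = TRUE),
                   stringsAsFactors = FALSE, check.names = FALSE,
                   row.names = NULL)
  names(df)[1] <- idcol
  df
}

df_to_fingerprints <- function(df) {
  fps <- lapply(strsplit(as.character(df$bits), " ", fixed = TRUE),
                function(b) sort(as.integer(b[nzchar(b)])))
  names(fps) <- as.character(df$compound_id)
  fps
}

cohort_files <- c(compounds = "compounds.csv",
                  chem = "chem_descriptors.csv",
                  qhts = "qhts.csv",
                  fingerprints = "fingerprints.csv",
                  bioactivity = "bioactivity.csv",
                  bio_fingerprints = "bio_fingerprints.csv",
                  mechanisms = "latent_mechanisms.csv",
                  bio_mechanisms = "bio_latent_mechanisms.csv",
                  fp_bits = "mechanism_fingerprint_bits.csv",
                  target_links = "target_links.csv",
                  clusters = "scaffold_clusters.csv",
                  cluster_effects = "scaffold_cluster_effects.csv",
                  config = "config.json")

#' Write a cohort to a directory of plain-text files
#'
#' One RFC-4180 CSV per table (compounds + pLD50, chemical descriptors,
#' long-format qHTS, long-format bioactivity, sparse fingerprints as
#' space-separated bit lists) plus the configuration as JSON.  Numeric
#' values are written with 17 significant digits so that
#' \code{read_cohort(write_cohort(x))} reproduces every double exactly.
#'
#' @param cohort a \code{tox_cohort}.
#' @param directory output directory; created if absent.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "tox_cohort"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  fp <- function(f) file.path(directory, f)

  write_num_csv(data.frame(compound_id = cohort$compound_ids,
                           pld50 = as.numeric(cohort$pld50),
                           stringsAsFactors = FALSE),
                fp(cohort_files[["compounds"]]))
  write_num_csv(matrix_to_df(cohort$chem_descriptors),
                fp(cohort_files[["chem"]]))
  write_num_csv(cohort$qhts, fp(cohort_files[["qhts"]]))
  write_num_csv(fingerprints_to_df(cohort$fingerprints),
                fp(cohort_files[["fingerprints"]]))
  write_num_csv(cohort$bioactivity, fp(cohort_files[["bioactivity"]]))
  write_num_csv(fingerprints_to_df(cohort$bio_fingerprints),
                fp(cohort_files[["bio_fingerprints"]]))
  write_num_csv(matrix_to_df(cohort$truth$mechanisms),
                fp(cohort_files[["mechanisms"]]))
  write_num_csv(matrix_to_df(cohort$truth$bio_mechanisms),
                fp(cohort_files[["bio_mechanisms"]]))
  write_num_csv(fingerprints_to_df(cohort$truth$fp_bits,
                                   idcol = "mechanism"),
                fp(cohort_files[["fp_bits"]]))
  write_num_csv(data.frame(target_id = names(cohort$truth$target_mech),
                           mechanism = as.integer(cohort$truth$target_mech),
                           stringsAsFactors = FALSE),
                fp(cohort_files[["target_links"]]))
  write_num_csv(data.frame(compound_id = names(cohort$truth$cluster),
                           cluster = as.integer(cohort$truth$cluster),
                           stringsAsFactors = FALSE),
                fp(cohort_files[["clusters"]]))
  write_num_csv(data.frame(cluster = seq_along(cohort$truth$cluster_effect),
                           effect = cohort$truth$cluster_effect,
                           stringsAsFactors = FALSE),
                fp(cohort_files[["cluster_effects"]]))
  cfg <- unclass(cohort$config)
  cfg$domain_signal_weights <- as.list(cfg$domain_signal_weights)
  jsonlite::write_json(cfg, fp(cohort_files[["config"]]),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(directory, cohort_files))
}

read_cohort_csv <- function(directory, key, required_cols) {
  path <- file.path(directory, cohort_files[[key]])
  if (!file.exists(path))
    stop("read_cohort: missing file '", cohort_files[[key]], "' in ",
         directory, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = NA)
  missing <- setdiff(required_cols, colnames(df))
  if (length(missing))
    stop("read_cohort: file '", cohort_files[[key]], "' lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing the cohort files.
#' @return A \code{tox_cohort} equal (to full numeric precision) to the one
#'   written.
#' @export
read_cohort <- function(directory) {
  if (!dir.exists(directory))
    stop("read_cohort: directory not found: ", directory, call. = FALSE)
  cfg_path <- file.path(directory, cohort_files[["config"]])
  if (!file.exists(cfg_path))
    stop("read_cohort: missing file '", cohort_files[["config"]], "' in ",
         directory, call. = FALSE)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  cfg$domain_signal_weights <- unlist(cfg$domain_signal_weights)
  config <- do.call(synth_config, cfg)

  cmp <- read_cohort_csv(directory, "compounds", c("compound_id", "pld50"))
  chem <- read_cohort_csv(directory, "chem", "compound_id")
  qhts <- read_cohort_csv(directory, "qhts",
                          c("compound_id", "cell_line", "concentration_uM",
                            "response"))
  fps <- read_cohort_csv(directory, "fingerprints", c("compound_id", "bits"))
  bio <- read_cohort_csv(directory, "bioactivity",
                         c("compound_id", "target_id", "active"))
  bio_fps <- read_cohort_csv(directory, "bio_fingerprints",
                             c("compound_id", "bits"))
  mech <- read_cohort_csv(directory, "mechanisms", "compound_id")
  bio_mech <- read_cohort_csv(directory, "bio_mechanisms", "compound_id")
  fp_bits_df <- read_cohort_csv(directory, "fp_bits", c("mechanism", "bits"))
  links <- read_cohort_csv(directory, "target_links",
                           c("target_id", "mechanism"))
  clus <- read_cohort_csv(directory, "clusters",
                          c("compound_id", "cluster"))
  clus_eff <- read_cohort_csv(directory, "cluster_effects",
                              c("cluster", "effect"))

  ids <- as.character(cmp$compound_id)
  chem_m <- as.matrix(chem[, setdiff(colnames(chem), "compound_id"),
                           drop = FALSE])
  storage.mode(chem_m) <- "double"
  rownames(chem_m) <- as.character(chem$compound_id)
  mech_m <- as.matrix(mech[, setdiff(colnames(mech), "compound_id"),
                           drop = FALSE])
  storage.mode(mech_m) <- "double"
  rownames(mech_m) <- as.character(mech$compound_id)
  bio_mech_m <- as.matrix(bio_mech[, setdiff(colnames(bio_mech),
                                             "compound_id"), drop = FALSE])
  storage.mode(bio_mech_m) <- "double"
  rownames(bio_mech_m) <- as.character(bio_mech$compound_id)
  names(fp_bits_df)[names(fp_bits_df) == "mechanism"] <- "compound_id"
  qhts$compound_id <- as.character(qhts$compound_id)
  qhts$cell_line <- as.character(qhts$cell_line)
  bio$compound_id <- as.character(bio$compound_id)
  bio$target_id <- as.character(bio$target_id)
  bio$active <- as.integer(bio$active)

  facing <- mechanism_facing(config$n_latent_mechanisms,
                             config$n_nuisance_mechanisms)
  structure(list(compound_ids = ids,
                 fingerprints = df_to_fingerprints(fps),
                 chem_descriptors = chem_m,
                 qhts = qhts,
                 pld50 = stats::setNames(as.numeric(cmp$pld50), ids),
                 bioactivity = bio,
                 bio_fingerprints = df_to_fingerprints(bio_fps),
                 config = config,
                 truth = list(mechanisms = mech_m,
                              facing = facing,
                              fp_bits = df_to_fingerprints(fp_bits_df),
                              target_mech = stats::setNames(
                                as.integer(links$mechanism),
                                as.character(links$target_id)),
                              bio_mechanisms = bio_mech_m,
                              cluster = stats::setNames(
                                as.integer(clus$cluster),
                                as.character(clus$compound_id)),
                              cluster_effect = as.numeric(clus_eff$effect))),
            class = "tox_cohort")
}
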