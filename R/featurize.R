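#' Classify pLD50 values into toxicity classes
#'
#' Applies the study thresholds: pLD50 < \code{low} is nontoxic,
#' pLD50 > \code{high} is toxic, and everything in between (boundaries
#' included, the inequalities are strict) is marginal and excluded from
#' modelling.  pLD50 is -log10 of the median lethal dose in mol/kg, so
#' larger values mean greater acute toxicity.
#'
#' @param pld50 numeric vector of pLD50 values; must be finite.
#' @param low,high class thresholds (defaults 2 and 3).
#' @return Character vector in \code{c("nontoxic", "marginal", "toxic")}.
#' @examples
#' classify_toxicity(c(1.5, 2, 2.5, 3, 3.5))
#' @export
classify_toxicity <- function(pld50, low = 2, high = 3) {
  if (any(!is.finite(pld50)))
    stop("classify_toxicity: pLD50 values must be finite", call. = FALSE)
  ifelse(pld50 < low, "nontoxic", ifelse(pld50 > high, "toxic", "marginal"))
}

#' Scale a qHTS dose-response profile to unit maximum
#'
#' Divides every response in the profile by the profile's maximum response,
#' so the scaled maximum is exactly 1.  Profiles with no measurable
#' cytotoxicity (maximum response <= 0) map to all zeros, carrying a
#' \code{no_response} attribute; dividing by a nonpositive maximum would
#' flip response signs.  The operation is idempotent.
#'
#' @param responses numeric response vector of one compound/cell-line curve.
#' @return Scaled responses; attribute \code{no_response} is TRUE for the
#'   degenerate all-zero case.
#' @export
scale_qhts_profile <- function(responses) {
  stopifnot(is.numeric(responses), length(responses) >= 1L)
  m <- max(responses)
  if (m <= 0)
    return(structure(rep(0, length(responses)), no_response = TRUE))
  responses / m
}

#' Build the cytotoxicity descriptor block from long-format qHTS data
#'
#' Validates that every compound x cell-line profile has exactly the shared
#' number of strictly increasing concentrations, scales each profile to
#' unit maximum with [scale_qhts_profile()], and lays the results out as
#' one column per (cell line, concentration index) pair -- 182 columns for
#' the canonical 13-line, 14-point panel.
#'
#' @param qhts data.frame with columns \code{compound_id},
#'   \code{cell_line}, \code{concentration_uM}, \code{response}.
#' @return Numeric matrix, compounds x (cell lines * concentrations), with
#'   columns named \code{<cell_line>_c<index>}.
#' @export
qhts_block <- function(qhts) {
  stopifnot(is.data.frame(qhts),
            all(c("compound_id", "cell_line", "concentration_uM",
                  "response") %in% names(qhts)))
  ids <- unique(qhts$compound_id)
  cells <- sort(unique(qhts$cell_line))
  grid <- sort(unique(qhts$concentration_uM))
  n_conc <- length(grid)
  if (any(diff(grid) <= 0))
    stop("qhts_block: concentrations must be strictly increasing",
         call. = FALSE)
  cols <- as.vector(t(outer(cells, seq_len(n_conc),
                            function(cl, j) sprintf("%s_c%02d", cl, j))))
  out <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(ids, cols))
  key <- split(seq_len(nrow(qhts)), list(qhts$compound_id, qhts$cell_line),
               drop = TRUE)
  for (nm in names(key)) {
    rows <- key[[nm]]
    prof <- qhts[rows, ]
    if (nrow(prof) != n_conc ||
        !isTRUE(all.equal(sort(prof$concentration_uM), grid)))
      stop("qhts_block: profile '", nm, "' does not cover the shared ",
           n_conc, "-point concentration grid", call. = FALSE)
    ord <- order(prof$concentration_uM)
    scaled <- scale_qhts_profile(prof$response[ord])
    i <- match(prof$compound_id[1], ids)
    js <- sprintf("%s_c%02d", prof$cell_line[1], seq_len(n_conc))
    out[i, js] <- scaled
  }
  if (anyNA(out)) {
    bad <- ids[apply(out, 1, anyNA)]
    stop("qhts_block: incomplete qHTS panel for compound(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Assemble the three-domain descriptor table and class labels
#'
#' Joins the chemical, protein-target and cytotoxicity descriptor blocks on
#' compound id (intersection semantics: a compound missing from any block
#' is excluded and reported), classifies compounds by pLD50, removes the
#' marginal class, and returns a single numeric descriptor matrix whose
#' columns carry a domain tag plus binary toxic/nontoxic labels.
#'
#' @param chem numeric matrix of chemical descriptors (rownames = ids).
#' @param target numeric matrix of target-affinity scores (rownames = ids).
#' @param cytotox numeric matrix from [qhts_block()] (rownames = ids).
#' @param tox data.frame with columns \code{compound_id}, \code{pld50}.
#' @param low,high thresholds passed to [classify_toxicity()].
#' @return List with \code{table} (descriptor matrix with a \code{domain}
#'   attribute, one tag per column), \code{labels} (factor with levels
#'   nontoxic, toxic), \code{dropped_incomplete} (ids missing from a
#'   block) and \code{dropped_marginal}.
#' @export
assemble_table <- function(chem, target, cytotox, tox, low = 2, high = 3) {
  stopifnot(is.matrix(chem), is.matrix(target), is.matrix(cytotox),
            is.data.frame(tox),
            all(c("compound_id", "pld50") %in% names(tox)))
  ids <- as.character(tox$compound_id)
  shared <- Reduce(intersect, list(ids, rownames(chem), rownames(target),
                                   rownames(cytotox)))
  dropped_incomplete <- setdiff(
    unique(c(ids, rownames(chem), rownames(target), rownames(cytotox))),
    shared)
  cls <- classify_toxicity(tox$pld50[match(shared, ids)], low, high)
  dropped_marginal <- shared[cls == "marginal"]
  keep <- shared[cls != "marginal"]
  if (length(keep) == 0L)
    stop("assemble_table: empty modeling table (all compounds marginal or ",
         "incomplete)", call. = FALSE)
  tab <- cbind(chem[keep, , drop = FALSE],
               target[keep, , drop = FALSE],
               cytotox[keep, , drop = FALSE])
  if (anyDuplicated(colnames(tab)))
    stop("assemble_table: descriptor column names must be unique",
         call. = FALSE)
  if (anyNA(tab))
    stop("assemble_table: descriptor table contains missing values",
         call. = FALSE)
  attr(tab, "domain") <- c(rep("chemical", ncol(chem)),
                           rep("target", ncol(target)),
                           rep("cytotox", ncol(cytotox)))
  labels <- factor(cls[cls != "marginal"], levels = c("nontoxic", "toxic"))
  names(labels) <- keep
  list(table = tab,
       labels = labels,
       dropped_incomplete = dropped_incomplete,
       dropped_marginal = dropped_marginal)
}

#' Column domain tags of a descriptor table
#' @param table a descriptor matrix from [assemble_table()] (or any matrix
#'   carrying a \code{domain} attribute).
#' @return Character vector, one of chemical/target/cytotox per column.
#' @export
domains <- function(table) {
  d <- attr(table, "domain")
  if (is.null(d))
    stop("domains: table carries no domain tags", call. = FALSE)
  d
}

#' Restrict a descriptor table to a combination of domains
#' @inheritParams domains
#' @param combo non-empty subset of c("chemical", "target", "cytotox").
#' @return The column-subset matrix, domain tags preserved.
#' @export
select_domains <- function(table, combo) {
  combo <- match.arg(combo, c("chemical", "target", "cytotox"),
                     several.ok = TRUE)
  d <- domains(table)
  keep <- d %in% combo
  out <- table[, keep, drop = FALSE]
  attr(out, "domain") <- d[keep]
  out
}

#' Featurize a synthetic cohort end to end
#'
#' Trains the [lmnb()] scorer on the cohort's bioactivity table, scores the
#' cohort compounds, builds the cytotoxicity block with [qhts_block()], and
#' assembles the full domain-tagged descriptor table with
#' [assemble_table()].
#'
#' @param cohort a \code{tox_cohort} from [generate_cohort()] or
#'   [read_cohort()].
#' @param min_records record-count threshold for the target scorer.
#' @return As [assemble_table()], plus the fitted \code{scorer}.
#' @export
featurize_cohort <- function(cohort, min_records = 50L) {
  stopifnot(inherits(cohort, "tox_cohort"))
  scorer <- lmnb(cohort$bioactivity, cohort$bio_fingerprints,
                 min_records = min_records)
  target_scores <- predict(scorer, cohort$fingerprints)
  colnames(target_scores) <- paste0("tgt_", colnames(target_scores))
  cyto <- qhts_block(cohort$qhts)
  out <- assemble_table(cohort$chem_descriptors, target_scores, cyto,
                        data.frame(compound_id = cohort$compound_ids,
                                   pld50 = as.numeric(cohort$pld50),
                                   stringsAsFactors = FALSE))
  out$scorer <- scorer
  out
}
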