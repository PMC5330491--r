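#' Rating scale of the radiologic consensus
#'
#' Every follow-up is rated on a 6-level nominal scale:
#' 0 initial diagnosis, 1 immediate postoperative MRI, 2 disease regression,
#' 3 stable disease, 4 uncertain disease progression (e.g. possible
#' pseudo-progression after radiotherapy), 5 disease progression.
#'
#' @return integer vector of valid categories.
#' @export
rating_levels <- function() 0:5

.check_ratings <- function(x) {
  x <- as.integer(x)
  if (any(is.na(x)) || any(!x %in% rating_levels()))
    stop("ratings must be integers on the 0-5 scale")
  x
}

#' Cohen's kappa for two aligned raters
#'
#' Chance-corrected agreement on a nominal scale:
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o and chance
#' agreement p_e from the two raters' marginal category frequencies. When
#' both raters are constant and identical (p_e = 1) agreement is perfect by
#' construction and kappa is defined as 1.
#'
#' @param ratings_a,ratings_b equal-length vectors of categories, aligned
#'   scan by scan.
#' @return kappa in [-1, 1].
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length")
  if (length(ratings_a) == 0) stop("empty rating vectors")
  a <- as.character(ratings_a); b <- as.character(ratings_b)
  lev <- sort(unique(c(a, b)))
  pa <- table(factor(a, lev)) / length(a)
  pb <- table(factor(b, lev)) / length(b)
  po <- mean(a == b)
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Hierarchical multidisciplinary consensus label
#'
#' Resolves the multidisciplinary consensus (MC) rating for each scan by a
#' fixed evidence hierarchy: histopathology when available (tier 1), else
#' the CNS tumor-board decision (tier 2), else the post-consensus
#' radiologic rating (tier 3, always present).
#'
#' @param histo,board,rc vectors of ratings on the 0-5 scale; \code{histo}
#'   and \code{board} may contain NA where unavailable, \code{rc} may not.
#' @return data.frame with columns \code{mc} (resolved rating) and
#'   \code{tier} (1 = histopathology, 2 = tumor board, 3 = RC).
#' @export
resolve_mc <- function(histo, board, rc) {
  rc <- .check_ratings(rc)
  n <- length(rc)
  histo <- if (is.null(histo)) rep(NA_integer_, n) else as.integer(histo)
  board <- if (is.null(board)) rep(NA_integer_, n) else as.integer(board)
  stopifnot(length(histo) == n, length(board) == n)
  mc <- ifelse(!is.na(histo), histo, ifelse(!is.na(board), board, rc))
  tier <- ifelse(!is.na(histo), 1L, ifelse(!is.na(board), 2L, 3L))
  data.frame(mc = as.integer(mc), tier = tier)
}

#' Dichotomize ratings into the progression endpoint
#'
#' Maps the 0-5 rating to the binary "disease progression" outcome of the
#' classifier. Initial-diagnosis (0) and immediate postoperative (1) scans
#' are excluded from modeling (postoperative volume collapse would dominate
#' and bias the model). Category 5 is progression; 2 and 3 are not; whether
#' the uncertain category 4 counts as progression is configurable and
#' defaults to "no".
#'
#' @param rating vector of 0-5 ratings.
#' @param progression_categories categories counting as progression
#'   (default 5; use \code{c(4, 5)} for the inclusive mapping).
#' @return integer vector: 1 progression, 0 no progression, NA excluded.
#' @export
dichotomize <- function(rating, progression_categories = 5L) {
  r <- .check_ratings(rating)
  stopifnot(all(progression_categories %in% 2:5))
  out <- ifelse(r %in% c(0L, 1L), NA_integer_,
                as.integer(r %in% progression_categories))
  out
}

#' Label a cohort's change records from its consensus ratings
#'
#' Joins MC-derived progression labels onto change records: resolves MC per
#' scan from the rating sources, dichotomizes, and attaches the label to the
#' change record of the pair ending at that scan.
#'
#' @param records change records from \code{\link{change_records}}.
#' @param mc_sources data.frame with \code{patient_id}, \code{scan_index},
#'   \code{histo}, \code{board}, \code{rc}.
#' @param progression_categories see \code{\link{dichotomize}}.
#' @return records with columns \code{mc}, \code{mc_tier} and
#'   \code{progression} (NA rows = structurally excluded scans).
#' @export
label_records <- function(records, mc_sources, progression_categories = 5L) {
  stopifnot(all(c("patient_id", "scan_index", "rc") %in% names(mc_sources)))
  res <- resolve_mc(mc_sources$histo, mc_sources$board, mc_sources$rc)
  lab <- data.frame(patient_id = mc_sources$patient_id,
                    scan_index = mc_sources$scan_index,
                    mc = res$mc, mc_tier = res$tier)
  lab$progression <- dichotomize(lab$mc, progression_categories)
  records$progression <- NULL
  merge(records, lab, by = c("patient_id", "scan_index"),
        all.x = TRUE, sort = FALSE)
}
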