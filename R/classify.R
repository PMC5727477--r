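#' Process labels recognised by the classifier
#' @export
assembly_labels <- function() {
  c("homogeneous_selection", "variable_selection",
    "dispersal_limitation_drift", "homogenizing_dispersal",
    "weak_homogeneous_selection", "undominated", "undefined")
}

#' Two-sided normal critical value for the selection thresholds
#'
#' The betaNTI/betaNRI classification thresholds of +-2 approximate the
#' two-sided standard-normal critical value at the given error level
#' (1.96 at 5%).
#'
#' @param alpha Two-sided error level (default 0.05).
#' @return The critical value `qnorm(1 - alpha / 2)`.
#' @export
deviation_threshold <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  qnorm(1 - alpha / 2)
}

#' Classify sample pairs into assembly processes
#'
#' Applies the decision rules to per-pair (betaNTI, RC_bray):
#' `bnti < -2` homogeneous selection; `bnti > +2` variable selection;
#' otherwise RC_bray partitions the stochastic mass: `rc > +0.95`
#' dispersal limitation coupled with drift; `rc < -0.95` homogenizing
#' dispersal when dispersal is possible, weak homogeneous selection in a
#' closed system (`dispersal_possible = FALSE`); `|rc| <= 0.95`
#' undominated. All inequalities are strict; a betaNTI or RC value landing
#' exactly on a threshold is assigned `"undominated"` (reported via
#' `message()`). An `NA` betaNTI (undefined deviation) yields the label
#' `"undefined"`, as does a missing RC value when it is needed.
#'
#' @param bnti Numeric vector of betaNTI deviations (NA = undefined).
#' @param rc Numeric vector of RC_bray values in \[-1, 1\], or `NULL` when
#'   all pairs are selection-classified.
#' @param dispersal_possible Logical flag for the whole run: `FALSE` for
#'   closed systems with no dispersal between communities.
#' @param bnti_threshold,rc_threshold Classification thresholds (defaults
#'   2 and 0.95).
#' @return Character vector of labels (see [assembly_labels()]).
#' @export
#' @examples
#' classify_pairs(c(-2.51, 0.3, 0.3, 2.5),
#'                c(NA, 0.99, -0.99, NA), dispersal_possible = FALSE)
classify_pairs <- function(bnti, rc = NULL, dispersal_possible = TRUE,
                           bnti_threshold = 2, rc_threshold = 0.95) {
  if (bnti_threshold <= 0 || rc_threshold <= 0)
    stop("thresholds must be positive")
  n <- length(bnti)
  if (is.null(rc)) rc <- rep(NA_real_, n)
  if (length(rc) != n) stop("bnti and rc lengths differ")
  if (any(rc < -1 - 1e-12 | rc > 1 + 1e-12, na.rm = TRUE))
    stop("rc values must lie in [-1, 1]")
  lab <- rep("undefined", n)
  sel_lo <- !is.na(bnti) & bnti < -bnti_threshold
  sel_hi <- !is.na(bnti) & bnti > bnti_threshold
  on_thr <- !is.na(bnti) & abs(bnti) == bnti_threshold
  stoch <- !is.na(bnti) & !sel_lo & !sel_hi
  lab[sel_lo] <- "homogeneous_selection"
  lab[sel_hi] <- "variable_selection"
  if (any(on_thr)) {
    message(sprintf("%d pair(s) exactly on the |betaNTI| = %g boundary assigned undominated",
                    sum(on_thr), bnti_threshold))
    lab[on_thr] <- "undominated"
  }
  need_rc <- stoch & !on_thr
  if (any(need_rc & is.na(rc))) {
    message(sprintf("%d stochastic-branch pair(s) without an RC value left undefined",
                    sum(need_rc & is.na(rc))))
  }
  ok <- need_rc & !is.na(rc)
  lab[ok & rc > rc_threshold] <- "dispersal_limitation_drift"
  lab[ok & rc < -rc_threshold] <-
    if (dispersal_possible) "homogenizing_dispersal"
    else "weak_homogeneous_selection"
  lab[ok & abs(rc) <= rc_threshold] <- "undominated"
  n_on_rc <- sum(ok & abs(rc) == rc_threshold)
  if (n_on_rc > 0)
    message(sprintf("%d pair(s) exactly on the |RC| = %g boundary assigned undominated",
                    n_on_rc, rc_threshold))
  lab
}

#' Classify a single pair
#'
#' Scalar convenience wrapper around [classify_pairs()].
#'
#' @inheritParams classify_pairs
#' @return A single label.
#' @export
classify_pair <- function(bnti, rc = NA_real_, dispersal_possible = TRUE,
                          bnti_threshold = 2, rc_threshold = 0.95) {
  stopifnot(length(bnti) == 1L, length(rc) == 1L)
  classify_pairs(bnti, rc, dispersal_possible, bnti_threshold, rc_threshold)
}

#' Aggregate process labels into fractions
#'
#' Fractions are computed over defined pairs and sum to 1; the undefined
#' count is reported separately so the accounting is auditable. All seven
#' categories are always present in the output.
#'
#' @param labels Character vector of labels from [classify_pairs()].
#' @param dispersal_possible Flag recorded with the result (weak
#'   homogeneous selection and homogenizing dispersal are mutually
#'   exclusive across a run).
#' @return Object of class `"assembly_fractions"`: `counts`, `fractions`,
#'   `n_defined`, `n_undefined`, `dispersal_possible`.
#' @export
process_fractions <- function(labels, dispersal_possible = TRUE) {
  known <- assembly_labels()
  bad <- setdiff(unique(labels), known)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  defined_labels <- setdiff(known, "undefined")
  n_def <- sum(labels != "undefined")
  if (n_def == 0L) stop("no defined pairs to aggregate")
  counts <- vapply(known, function(l) sum(labels == l), integer(1))
  fractions <- counts[defined_labels] / n_def
  structure(list(counts = counts, fractions = fractions,
                 n_defined = n_def,
                 n_undefined = sum(labels == "undefined"),
                 dispersal_possible = dispersal_possible),
            class = "assembly_fractions")
}

#' @export
print.assembly_fractions <- function(x, ...) {
  cat(sprintf("Assembly process fractions over %d defined pair(s)%s\n",
              x$n_defined,
              if (x$n_undefined) sprintf(" (+%d undefined)", x$n_undefined)
              else ""))
  for (l in names(x$fractions))
    cat(sprintf("  %-28s %6.1f%%  (n = %d)\n", l, 100 * x$fractions[[l]],
                x$counts[[l]]))
  invisible(x)
}

#' Classify all pairs of a betaNTI / RC-bray analysis
#'
#' Joins a [beta_nti()] result with a matching [raup_crick_bray()] result
#' into a per-pair label table plus aggregate fractions.
#'
#' @param bnti A `"beta_deviation"` object (betaNTI).
#' @param rc A `"raup_crick"` object over the same samples, or `NULL`.
#' @param dispersal_possible See [classify_pairs()].
#' @param bnti_threshold,rc_threshold Classification thresholds.
#' @return List with `pairs` (data.frame: sample_i, sample_j, bnti, rc,
#'   label) and `fractions` (an `"assembly_fractions"`).
#' @export
classify_assembly <- function(bnti, rc = NULL, dispersal_possible = TRUE,
                              bnti_threshold = 2, rc_threshold = 0.95) {
  stopifnot(inherits(bnti, "beta_deviation"))
  tab <- pair_table(bnti)
  rcv <- rep(NA_real_, nrow(tab))
  if (!is.null(rc)) {
    stopifnot(inherits(rc, "raup_crick"))
    if (!setequal(rownames(rc$rc), rownames(bnti$deviation)))
      stop("betaNTI and RC-bray cover different samples")
    rcv <- rc$rc[cbind(tab$sample_i, tab$sample_j)]
  }
  lab <- classify_pairs(tab$deviation, rcv, dispersal_possible,
                        bnti_threshold, rc_threshold)
  pairs <- data.frame(sample_i = tab$sample_i, sample_j = tab$sample_j,
                      bnti = tab$deviation, rc = rcv, label = lab,
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       fractions = process_fractions(lab, dispersal_possible))
}
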