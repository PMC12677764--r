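# Cross-engine comparison: element-wise tolerance criterion, match score,
# pairwise aggregation per model, reproducibility-level classification, and
# corpus summaries.
#
# Two result sets match when every element agrees to a relative tolerance of
# 1e-4 with an absolute tolerance scaled by the range of output values of
# that variable (allclose-style). The match score is the maximum
# tolerance-normalized deviation, so score <= 1 is exactly the match cutoff.

#' Comparison configuration
#'
#' @param rtol relative tolerance of the element-wise criterion.
#' @param range_atol_scale factor applied to each column's value range to
#'   obtain its absolute tolerance.
#' @param score_cutoff score at or below which a pair is declared a match.
#' @return a `comparison_config`.
#' @export
comparison_config <- function(rtol = 1e-4, range_atol_scale = 1e-4,
                              score_cutoff = 1) {
  stopifnot(rtol > 0, range_atol_scale > 0, score_cutoff > 0)
  structure(list(rtol = rtol, range_atol_scale = range_atol_scale,
                 score_cutoff = score_cutoff), class = "comparison_config")
}

#' Compare two run results
#'
#' For each output column `v`, the absolute tolerance is
#' `range_atol_scale * (max(v) - min(v))` over both results jointly, and the
#' per-element deviation ratio is `|a - b| / (atol_v + rtol * max(|a|,|b|))`
#' (with 0/0 defined as 0). The column score is the maximum ratio, the
#' overall score the maximum over columns, and the pair matches iff the
#' score is at most `score_cutoff`. Using `max(|a|,|b|)` makes the
#' comparison symmetric in its operands. Pairs with failed runs, differing
#' report shapes or labels, or non-finite values are `incomparable`.
#'
#' @param a,b `run_result` objects.
#' @param cfg a [comparison_config()].
#' @return a `pair_comparison`: engines, per-column scores, overall score,
#'   `matched`, `status`.
#' @export
compare_results <- function(a, b, cfg = comparison_config()) {
  out <- function(status, scores = numeric(0), score = NA_real_) {
    structure(list(engine_a = a$engine, engine_b = b$engine,
                   per_column_scores = scores, score = score,
                   matched = isTRUE(status == "compared" &&
                                    score <= cfg$score_cutoff),
                   status = status),
              class = "pair_comparison")
  }
  if (!identical(a$status, "succeeded") || !identical(b$status, "succeeded"))
    return(out("incomparable"))
  if (!setequal(names(a$reports), names(b$reports)))
    return(out("incomparable"))
  scores <- numeric(0)
  for (nm in names(a$reports)) {
    ma <- a$reports[[nm]]; mb <- b$reports[[nm]]
    if (!all(dim(ma) == dim(mb)) ||
        !identical(a$column_labels[[nm]], b$column_labels[[nm]]))
      return(out("incomparable"))
    if (any(!is.finite(ma)) || any(!is.finite(mb)))
      return(out("incomparable"))
    for (j in seq_len(ncol(ma))) {
      va <- ma[, j]; vb <- mb[, j]
      rng <- max(va, vb) - min(va, vb)
      atol <- cfg$range_atol_scale * rng
      denom <- atol + cfg$rtol * pmax(abs(va), abs(vb))
      num <- abs(va - vb)
      r <- ifelse(num == 0, 0, num / denom)
      scores[[paste0(nm, ":", a$column_labels[[nm]][j])]] <- max(r)
    }
  }
  out("compared", scores, if (length(scores)) max(scores) else 0)
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("<pair_comparison> %s vs %s: %s", x$engine_a, x$engine_b,
              x$status))
  if (x$status == "compared")
    cat(sprintf(", score %.4g -> %s", x$score,
                if (x$matched) "MATCH" else "no match"))
  cat("\n")
  invisible(x)
}

# largest subset of engines in which every pair matched (exact enumeration;
# intended for <= 8 engines)
max_agreement <- function(engines, matched_pairs) {
  n <- length(engines)
  if (n == 0L) return(0L)
  if (n == 1L || !length(matched_pairs)) return(1L)
  key <- function(x, y) paste(sort(c(x, y)), collapse = "|")
  mset <- vapply(matched_pairs, function(p) key(p[1], p[2]), "")
  for (size in seq(n, 2L, by = -1L)) {
    combos <- utils::combn(engines, size, simplify = FALSE)
    for (cs in combos) {
      prs <- utils::combn(cs, 2, simplify = FALSE)
      if (all(vapply(prs, function(p) key(p[1], p[2]) %in% mset, TRUE)))
        return(as.integer(size))
    }
  }
  1L
}

#' Aggregate engine runs of one model into a verification record
#'
#' All unordered pairs of succeeded runs are compared; `agreement_size` is
#' the size of the largest engine subset in which every pair matched (1 if
#' anything succeeded but nothing matched, 0 if nothing succeeded). A model
#' is `verified` when at least one pair matched.
#'
#' @param model_id model identifier.
#' @param provenance `"template"`, `"curation"` or `"unknown"`.
#' @param runs list of `run_result`s, one per engine (distinct names).
#' @param cfg a [comparison_config()].
#' @return a `model_verification`.
#' @export
aggregate_runs <- function(model_id, provenance, runs,
                           cfg = comparison_config()) {
  engines <- vapply(runs, `[[`, "", "engine")
  if (anyDuplicated(engines))
    stop("duplicate engine names: ",
         paste(engines[duplicated(engines)], collapse = ", "), call. = FALSE)
  ok <- vapply(runs, function(r) identical(r$status, "succeeded"), TRUE)
  succ <- runs[ok]
  pairs <- list()
  if (length(succ) >= 2) {
    idx <- utils::combn(length(succ), 2, simplify = FALSE)
    pairs <- lapply(idx, function(ij)
      compare_results(succ[[ij[1]]], succ[[ij[2]]], cfg))
  }
  matched <- Filter(function(p) isTRUE(p$matched), pairs)
  agreement <- if (!length(succ)) 0L
    else max_agreement(vapply(succ, `[[`, "", "engine"),
                       lapply(matched, function(p) c(p$engine_a, p$engine_b)))
  v <- structure(list(
    model_id = model_id, provenance = provenance,
    n_attempted = length(runs), n_succeeded = length(succ),
    pairs = pairs, n_matched = length(matched),
    agreement_size = agreement,
    verified = length(matched) >= 1), class = "model_verification")
  v$level <- classify_level(v)
  v
}

#' Classify the reproducibility level of a verification record
#'
#' A verified model with a template experiment shows functional
#' reproducibility (the model itself is robust to interpretation); a
#' verified model with a curation-derived experiment shows end-to-end
#' reproducibility. Unknown provenance is treated as template-like.
#'
#' @param v a `model_verification`.
#' @return `"functional"`, `"end_to_end"` or `"unverified"`.
#' @export
classify_level <- function(v) {
  if (!isTRUE(v$verified)) return("unverified")
  if (identical(v$provenance, "curation")) "end_to_end" else "functional"
}

#' @export
print.model_verification <- function(x, ...) {
  cat(sprintf("<model_verification> %s [%s]: %d/%d runs succeeded, %d/%d pairs matched, agreement %d -> %s\n",
              x$model_id, x$provenance, x$n_succeeded, x$n_attempted,
              x$n_matched, length(x$pairs), x$agreement_size, x$level))
  invisible(x)
}

#' Summarize a corpus of model verifications
#'
#' @param verifications list of `model_verification` records.
#' @return a `corpus_summary` with a histogram indexed by
#'   (runs succeeded, agreement size), run/pair totals, and per-level
#'   counts.
#' @export
summarize_corpus <- function(verifications) {
  E <- if (length(verifications))
    max(vapply(verifications, `[[`, 1L, "n_attempted")) else 0L
  hist <- matrix(0L, nrow = E + 1, ncol = E + 1,
                 dimnames = list(n_succeeded = 0:E, agreement_size = 0:E))
  totals <- list(runs_attempted = 0L, runs_succeeded = 0L, runs_failed = 0L,
                 pairs_compared = 0L, pairs_matched = 0L)
  levels <- c(functional = 0L, end_to_end = 0L, unverified = 0L)
  for (v in verifications) {
    hist[v$n_succeeded + 1L, v$agreement_size + 1L] <-
      hist[v$n_succeeded + 1L, v$agreement_size + 1L] + 1L
    totals$runs_attempted <- totals$runs_attempted + v$n_attempted
    totals$runs_succeeded <- totals$runs_succeeded + v$n_succeeded
    totals$runs_failed <- totals$runs_failed + v$n_attempted - v$n_succeeded
    totals$pairs_compared <- totals$pairs_compared + length(v$pairs)
    totals$pairs_matched <- totals$pairs_matched + v$n_matched
    levels[[v$level]] <- levels[[v$level]] + 1L
  }
  structure(list(histogram = hist, totals = totals, per_level = levels,
                 n_models = length(verifications)),
            class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat("<corpus_summary>", x$n_models, "models\n")
  cat(sprintf("  runs: %d attempted, %d succeeded, %d failed\n",
              x$totals$runs_attempted, x$totals$runs_succeeded,
              x$totals$runs_failed))
  cat(sprintf("  pairs: %d compared, %d matched\n",
              x$totals$pairs_compared, x$totals$pairs_matched))
  cat(sprintf("  levels: %d functional, %d end-to-end, %d unverified\n",
              x$per_level[["functional"]], x$per_level[["end_to_end"]],
              x$per_level[["unverified"]]))
  invisible(x)
}

# JSON-friendly representations -------------------------------------------

verification_to_list <- function(v) {
  list(model_id = v$model_id, provenance = v$provenance,
       n_attempted = v$n_attempted, n_succeeded = v$n_succeeded,
       n_matched = v$n_matched, agreement_size = v$agreement_size,
       verified = v$verified, level = v$level,
       pairs = lapply(v$pairs, function(p)
         list(engine_a = p$engine_a, engine_b = p$engine_b,
              status = p$status, score = p$score, matched = p$matched)))
}

summary_to_list <- function(s) {
  list(n_models = s$n_models,
       histogram = unclass(s$histogram),
       totals = s$totals, per_level = as.list(s$per_level))
}
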