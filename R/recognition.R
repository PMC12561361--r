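# Trajectory-to-text recognition by template matching of z-scored velocity
# profiles.

#' Build a velocity-template library from glyph templates
#'
#' Synthesizes each glyph's kinematics under the standard duration policy
#' and stores its per-dimension z-scored velocity profile, the search space
#' for template-matching recognition.
#'
#' @param templates a `glyph_corpus`, or list of [stroke_template()].
#' @param total_T optional fixed duration passed to
#'   [synthesize_kinematics()] (default: arclength policy).
#' @return object of class `template_library`: named list `entries` of
#'   z-scored n x 2 velocity matrices.
#' @export
build_library <- function(templates, total_T = NULL) {
  if (inherits(templates, "glyph_corpus")) templates <- templates$templates
  if (length(templates) < 2L) stop("a library needs at least 2 templates")
  ids <- vapply(templates, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate template ids in library")
  entries <- lapply(templates, function(tp)
    zscore_per_dim(velocity_matrix(synthesize_kinematics(tp, total_T = total_T))))
  names(entries) <- ids
  structure(list(entries = entries), class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("Template library: %d z-scored velocity templates\n",
              length(x$entries)))
  invisible(x)
}

#' Recognize a decoded trajectory against a template library
#'
#' The query velocity is z-scored per dimension and compared with every
#' library template, either by fastDTW distance (ascending; temporal
#' stretches tolerated) or by Pearson correlation after linear resampling
#' of both sequences to the query length (descending). Ties break by
#' lexicographic id.
#'
#' @param query velocity matrix (n x 2), [kinematic_series()], or vector.
#' @param library a [build_library()] object.
#' @param metric `"dtw"` (default) or `"cc"`.
#' @param truth optional true id; fills `top1_correct`.
#' @param radius fastDTW radius (default 2).
#' @return object of class `recognition_result`: `ranking` data frame
#'   (`id`, `score`), `top1`, `top1_correct`, `metric`.
#' @export
recognize <- function(query, library, metric = c("dtw", "cc"), truth = NA,
                      radius = 2L) {
  metric <- match.arg(metric)
  if (length(library$entries) == 0L) stop("empty template library")
  q <- zscore_per_dim(as_seq_matrix(query, "query"))
  ids <- names(library$entries)
  score <- vapply(library$entries, function(tmpl) {
    if (metric == "dtw") fast_dtw(tmpl, q, radius = radius)$distance
    else {
      a <- resample_linear(tmpl, nrow(q))
      stats::cor(as.vector(a), as.vector(q))
    }
  }, numeric(1L))
  ord <- order(if (metric == "dtw") score else -score, ids)
  ranking <- data.frame(id = ids[ord], score = score[ord],
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(ranking = ranking, top1 = ranking$id[1L],
                 top1_correct = if (is.na(truth)) NA else
                   identical(ranking$id[1L], as.character(truth)),
                 metric = metric),
            class = "recognition_result")
}

#' @export
print.recognition_result <- function(x, ...) {
  cat(sprintf("Recognition (%s): top-1 '%s'%s\n", x$metric, x$top1,
              if (is.na(x$top1_correct)) "" else
                if (x$top1_correct) " (correct)" else " (incorrect)"))
  print(utils::head(x$ranking, 5L))
  invisible(x)
}

# distance/similarity matrix between queries and library entries
recognition_scores <- function(queries, library, metric = "dtw", radius = 2L) {
  ids <- names(library$entries)
  out <- matrix(NA_real_, length(queries), length(ids),
                dimnames = list(NULL, ids))
  for (qi in seq_along(queries)) {
    q <- zscore_per_dim(as_seq_matrix(queries[[qi]]$v))
    out[qi, ] <- vapply(library$entries, function(tmpl) {
      if (metric == "dtw") fast_dtw(tmpl, q, radius = radius)$distance
      else {
        a <- resample_linear(tmpl, nrow(q))
        stats::cor(as.vector(a), as.vector(q))
      }
    }, numeric(1L))
  }
  out
}

top1_of_scores <- function(scores, metric) {
  ids <- colnames(scores)
  apply(scores, 1L, function(s) {
    ord <- order(if (metric == "dtw") s else -s, ids)
    ids[ord[1L]]
  })
}

#' Recognition rate as a function of library size
#'
#' Evaluates the mean and SD of the top-1 recognition rate when the library
#' is subsampled to each requested size. Every subsample is constrained to
#' contain all experiment characters (the query truths); at the experiment
#' size and the full library size the subsample is forced, so the SD is 0.
#'
#' @param queries list of queries, each a list with `id` (truth) and `v`
#'   (velocity matrix or [kinematic_series()]).
#' @param library a [build_library()] object (superset of the truths).
#' @param sizes integer vector of library sizes, all >= the number of
#'   distinct truth ids.
#' @param n_resamples random subsamples per size (default 1000).
#' @param seed integer seed.
#' @param metric `"dtw"` or `"cc"`.
#' @return data frame with `size`, `mean_rate`, `sd_rate`.
#' @export
recognition_curve <- function(queries, library, sizes, n_resamples = 1000L,
                              seed = 1L, metric = "dtw") {
  truth <- vapply(queries, function(q) as.character(q$id), character(1L))
  exp_ids <- sort(unique(truth))
  ids <- names(library$entries)
  if (!all(exp_ids %in% ids)) stop("library must contain all query truths")
  if (any(sizes < length(exp_ids)))
    stop("sizes must be >= the number of experiment characters")
  if (any(sizes > length(ids))) stop("sizes exceed library size")
  scores <- recognition_scores(queries, library, metric)
  extra <- setdiff(ids, exp_ids)
  rows <- lapply(sizes, function(sz) {
    n_extra <- sz - length(exp_ids)
    forced <- n_extra == 0L || n_extra == length(extra)
    reps <- if (forced) 1L else n_resamples
    rates <- with_seed(derive_seed(seed, "curve", sz), vapply(seq_len(reps),
      function(r) {
        sub <- c(exp_ids, if (n_extra > 0L) sample(extra, n_extra))
        pred <- top1_of_scores(scores[, sub, drop = FALSE], metric)
        mean(pred == truth)
      }, numeric(1L)))
    data.frame(size = sz, mean_rate = mean(rates),
               sd_rate = if (forced) 0 else stats::sd(rates))
  })
  do.call(rbind, rows)
}

#' Confusion matrix of recognition results
#'
#' @param results list of [recognize()] results; each must carry a `truth`
#'   attribute or be paired via `truth`.
#' @param truth optional character vector of true ids (recycled against
#'   `results`).
#' @return square table: rows = truth, columns = top-1 prediction; row sums
#'   equal the per-character query counts.
#' @export
confusion_matrix <- function(results, truth = NULL) {
  pred <- vapply(results, function(r) r$top1, character(1L))
  if (is.null(truth))
    truth <- vapply(results, function(r) attr(r, "truth") %||% NA_character_,
                    character(1L))
  ids <- sort(unique(c(truth, pred)))
  table(factor(truth, levels = ids), factor(pred, levels = ids),
        dnn = c("truth", "predicted"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
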