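mask_data <- function(x, what = "mask") {
  d <- if (is_volume(x)) x$data else x
  if (is.null(dim(d))) abort(sprintf("%s must be an array.", what))
  check_binary(d, what)
  d
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("shape mismatch: %s vs %s.",
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

#' Soft Dice loss
#'
#' The differentiable training loss
#' \deqn{L = 1 - \frac{2\sum p\,g + s}{\sum p + \sum g + s}}
#' over foreground probabilities `probs` and a binary target, with smoothing
#' constant `s` applied to numerator and denominator.
#'
#' @param probs numeric array of per-voxel foreground probabilities in `[0,1]`.
#' @param target a [binary_mask()] or binary array of the same shape.
#' @param smooth small positive smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(probs, target, smooth = 1e-5) {
  p <- if (is_volume(probs)) probs$data else probs
  g <- mask_data(target, "target")
  check_same_shape(p, g)
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9) abort("`probs` must lie in [0, 1].")
  1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
}

# gradient of dice_loss wrt probs; used by the network training path
dice_loss_grad <- function(p, g, smooth = 1e-5) {
  num <- 2 * sum(p * g) + smooth
  den <- sum(p) + sum(g) + smooth
  (num / den^2) - (2 * g / den)
}

#' Dice similarity coefficient between two binary masks
#'
#' \eqn{DSC = 2|P \cap G| / (|P| + |G|)}; defined as 1 when both masks are
#' empty, 0 when exactly one is empty.
#'
#' @param pred,gt binary masks (or arrays) of identical shape.
#' @return A fraction in `[0, 1]`.
#' @export
dice_score <- function(pred, gt) {
  p <- mask_data(pred, "pred"); g <- mask_data(gt, "gt")
  check_same_shape(p, g)
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(1)
  2 * sum(p * g) / (sp + sg)
}

#' Intersection over union (Jaccard index)
#'
#' \eqn{IoU = |P \cap G| / |P \cup G|}; 1 when both masks are empty. Related
#' to the Dice coefficient by \eqn{DSC = 2\,IoU/(1+IoU)}.
#'
#' @inheritParams dice_score
#' @return A fraction in `[0, 1]`.
#' @export
iou <- function(pred, gt) {
  p <- mask_data(pred, "pred"); g <- mask_data(gt, "gt")
  check_same_shape(p, g)
  inter <- sum(p * g)
  uni <- sum(p) + sum(g) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Extract boundary voxel coordinates of a binary mask
#'
#' Boundary = foreground voxels with at least one background face-neighbour
#' (6-connectivity); voxels on the array edge count as boundary, the outside
#' being background.
#'
#' @param m binary mask or array.
#' @return Integer matrix (n x 3) of 0-based voxel indices.
#' @export
boundary_voxels <- function(m) {
  x <- mask_data(m)
  d <- dim(x)
  pad <- array(0, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- x
  core <- function(sd, sh, sw) {
    pad[(2 + sd):(d[1] + 1 + sd), (2 + sh):(d[2] + 1 + sh), (2 + sw):(d[3] + 1 + sw)]
  }
  nb_min <- core(1, 0, 0)
  for (s in list(c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    nb_min <- pmin(nb_min, core(s[1], s[2], s[3]))
  }
  b <- (x == 1) & (nb_min == 0)
  which(b, arr.ind = TRUE) - 1L
}

#' 95th-percentile Hausdorff surface distance (mm)
#'
#' Extracts the boundary voxels of both masks, computes all directed
#' nearest-surface distances in millimetres in both directions, pools the two
#' directed sets, and returns the 95th percentile (linear interpolation).
#' Undefined (`NA`) when either mask is empty; such cases are excluded from
#' aggregate means by [aggregate_metrics()].
#'
#' @inheritParams dice_score
#' @param spacing mm per axis; defaults to the masks' spacing when they are
#'   [binary_mask()] objects.
#' @param percentile percentile of the pooled distance set (default 95).
#' @return Distance in mm, or `NA_real_` if either mask is empty.
#' @export
hausdorff95 <- function(pred, gt, spacing = NULL, percentile = 95) {
  p <- mask_data(pred, "pred"); g <- mask_data(gt, "gt")
  check_same_shape(p, g)
  if (is.null(spacing)) {
    spacing <- if (is_volume(pred)) pred$spacing else if (is_volume(gt)) gt$spacing else c(1, 1, 1)
  }
  if (is_volume(pred) && is_volume(gt) && max(abs(pred$spacing - gt$spacing)) > 1e-6) {
    abort("pred and gt have different voxel spacings.")
  }
  if (sum(p) == 0 || sum(g) == 0) return(NA_real_)
  bp <- boundary_voxels(p)
  bg <- boundary_voxels(g)
  dd <- surface_min_dists(bp * 1.0, bg * 1.0, as.numeric(spacing))
  unname(quantile(c(dd$da, dd$db), probs = percentile / 100, type = 7))
}

#' Aggregate per-case segmentation metrics into a report
#'
#' Retains every per-case row and adds arithmetic means; cases whose HD95 is
#' undefined (an empty prediction or reference) are excluded from the HD95
#' mean and counted.
#'
#' @param cases a data frame / tibble with columns `case`, `dsc`, `iou`,
#'   `hd95` (NA allowed), or a list of such rows.
#' @return A `metric_report`: list with `per_case` (tibble), `means` (named
#'   numeric), `n_hd95_excluded`.
#' @export
aggregate_metrics <- function(cases) {
  if (is.data.frame(cases)) {
    per_case <- as_tibble(cases)
  } else if (is.list(cases) && length(cases) > 0) {
    per_case <- dplyr::bind_rows(lapply(cases, as_tibble))
  } else {
    abort("`cases` must be a nonempty data frame or list of rows.")
  }
  if (nrow(per_case) == 0) abort("`cases` is empty.")
  needed <- c("case", "dsc", "iou", "hd95")
  missing_cols <- setdiff(needed, names(per_case))
  if (length(missing_cols) > 0) {
    abort(sprintf("`cases` lacks columns: %s.", paste(missing_cols, collapse = ", ")))
  }
  hd <- per_case$hd95
  structure(
    list(
      per_case = per_case[needed],
      means = c(
        dsc = mean(per_case$dsc),
        iou = mean(per_case$iou),
        hd95 = if (all(is.na(hd))) NA_real_ else mean(hd[!is.na(hd)])
      ),
      n_hd95_excluded = sum(is.na(hd))
    ),
    class = "metric_report"
  )
}

#' Evaluate a set of predicted masks against references
#'
#' @param preds,gts lists of [binary_mask()] objects, pairwise aligned.
#' @param ids optional case identifiers.
#' @return A `metric_report`.
#' @export
evaluate_masks <- function(preds, gts, ids = NULL) {
  stopifnot(length(preds) == length(gts), length(preds) > 0)
  if (is.null(ids)) ids <- paste0("case_", seq_along(preds))
  rows <- purrr::map2(preds, gts, function(p, g) {
    list(dsc = dice_score(p, g), iou = iou(p, g), hd95 = hausdorff95(p, g))
  })
  aggregate_metrics(tibble(
    case = as.character(ids),
    dsc = purrr::map_dbl(rows, "dsc"),
    iou = purrr::map_dbl(rows, "iou"),
    hd95 = purrr::map_dbl(rows, "hd95")
  ))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> %d cases | mean DSC %.4f, IoU %.4f, HD95 %s mm (%d case(s) excluded)\n",
    nrow(x$per_case), x$means[["dsc"]], x$means[["iou"]],
    ifelse(is.na(x$means[["hd95"]]), "NA", sprintf("%.3f", x$means[["hd95"]])),
    x$n_hd95_excluded
  ))
  print(x$per_case, ...)
  invisible(x)
}

#' @export
tidy.metric_report <- function(x, ...) x$per_case

#' @export
glance.metric_report <- function(x, ...) {
  tibble(
    n_cases = nrow(x$per_case),
    mean_dsc = x$means[["dsc"]],
    mean_iou = x$means[["iou"]],
    mean_hd95 = x$means[["hd95"]],
    n_hd95_excluded = x$n_hd95_excluded
  )
}

#' Write a metric report as CSV (per case) and JSON (means)
#'
#' @param report a `metric_report`.
#' @param dir output directory (created if needed).
#' @param stem file stem; writes `<stem>.csv` and `<stem>_summary.json`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_metric_report <- function(report, dir, stem = "metrics") {
  stopifnot(inherits(report, "metric_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  js <- file.path(dir, paste0(stem, "_summary.json"))
  write.csv(report$per_case, csv, row.names = FALSE)
  jsonlite::write_json(
    list(
      means = as.list(report$means),
      n_cases = nrow(report$per_case),
      n_hd95_excluded = report$n_hd95_excluded
    ),
    js, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(c(csv = csv, json = js))
}

#' @rdname autoplot_metaseg
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- pivot_metrics_long(object$per_case)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$case, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-case segmentation metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

pivot_metrics_long <- function(per_case) {
  dplyr::bind_rows(lapply(c("dsc", "iou", "hd95"), function(m) {
    tibble(case = per_case$case, metric = m, value = per_case[[m]])
  }))
}
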