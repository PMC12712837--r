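#' Per-voxel label atlas
#'
#' A label atlas maps every brain-view voxel (feature) to an integer
#' region or network label; label 0 marks unlabeled background. Every
#' nonzero label must have a name.
#'
#' @param labels integer vector, one label per voxel, aligned to the brain
#'   view's feature order.
#' @param names named character vector (or data.frame with columns
#'   `label`, `name`) mapping label ids to names.
#' @param family `"region"` or `"network"`.
#' @return A `label_atlas`.
#' @export
label_atlas <- function(labels, names, family = c("region", "network")) {
  family <- match.arg(family)
  labels <- as.integer(labels)
  if (is.data.frame(names))
    names <- setNames(as.character(names$name), names$label)
  used <- setdiff(unique(labels), 0L)
  missing <- setdiff(as.character(used), base::names(names))
  if (length(missing) > 0)
    stop("label_atlas: unnamed label id(s): ", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = names, family = family),
            class = "label_atlas")
}

#' Synthetic block atlas
#'
#' Partitions `q` voxels into `n_regions` contiguous, near-equal blocks —
#' a synthetic stand-in for an anatomical parcellation, sized to the
#' synthetic brain view.
#'
#' @param q number of voxels.
#' @param n_regions number of blocks.
#' @param family,prefix passed to the atlas labels.
#' @return A `label_atlas`.
#' @export
make_block_atlas <- function(q, n_regions = 10, family = "region",
                             prefix = family) {
  labels <- as.integer(cut(seq_len(q), n_regions, labels = FALSE))
  nm <- setNames(sprintf("%s_%02d", prefix, seq_len(n_regions)),
                 seq_len(n_regions))
  label_atlas(labels, nm, family = family)
}

#' Summarize brain weights by atlas label
#'
#' For every atlas label: the count and percentage of strictly positive
#' and strictly negative weight voxels (zeros counted in neither), and the
#' mean weight. Sorted by total nonzero percentage, descending — the
#' tabular equivalent of region/network spider plots of an LV's brain
#' pattern.
#'
#' @param v brain weight vector, aligned to the atlas.
#' @param atlas a [label_atlas()].
#' @return `data.frame` with columns `label`, `name`, `n_voxels`, `n_pos`,
#'   `n_neg`, `pct_pos`, `pct_neg`, `mean_weight`.
#' @export
summarize_weights_by_label <- function(v, atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (length(v) != length(atlas$labels))
    stop("summarize_weights_by_label: weight vector and atlas lengths differ")
  if (all(v == 0)) {
    warning("summarize_weights_by_label: all-zero weight vector, empty summary")
    return(data.frame(label = integer(0), name = character(0),
                      n_voxels = integer(0), n_pos = integer(0),
                      n_neg = integer(0), pct_pos = numeric(0),
                      pct_neg = numeric(0), mean_weight = numeric(0)))
  }
  used <- sort(setdiff(unique(atlas$labels), 0L))
  out <- do.call(rbind, lapply(used, function(l) {
    idx <- atlas$labels == l
    n <- sum(idx)
    n_pos <- sum(v[idx] > 0); n_neg <- sum(v[idx] < 0)
    data.frame(label = l, name = unname(atlas$names[as.character(l)]),
               n_voxels = n, n_pos = n_pos, n_neg = n_neg,
               pct_pos = 100 * n_pos / n, pct_neg = 100 * n_neg / n,
               mean_weight = mean(v[idx]))
  }))
  out <- out[order(out$pct_pos + out$pct_neg, decreasing = TRUE), ]
  rownames(out) <- NULL
  out
}
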