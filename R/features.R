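# Feature-quilt construction and masked mean pooling: each usable quilt cell
# gets a 128-d embedding; the per-patient image feature is the arithmetic
# mean over usable cells only, so white padding never dilutes it.

#' Embed an image quilt into a feature-quilt
#'
#' Cell (r, c) of the output holds the embedding of quilt cell (r, c); PAD
#' cells hold zeros and are masked out.
#'
#' @param encoder a trained [train_ssl()] encoder.
#' @param quilt an [build_quilt()] image quilt.
#' @return object of class `feature_quilt`: `tensor`
#'   (quilt_rows x quilt_cols x 128) and `usable_mask`.
#' @export
embed_quilt <- function(encoder, quilt) {
  stopifnot(inherits(quilt, "image_quilt"))
  ps <- quilt$patch_size
  mask <- quilt$usable_mask
  nr <- nrow(mask); nc <- ncol(mask)
  tensor <- array(0, c(nr, nc, 128L))
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) > 0) {
    patches <- lapply(seq_len(nrow(cells)), function(k) {
      r <- cells[k, 1]; c <- cells[k, 2]
      px <- quilt$pixels[((r - 1) * ps + 1):(r * ps), ((c - 1) * ps + 1):(c * ps), ,
                         drop = FALSE]
      dim(px) <- c(ps, ps, 3)
      px
    })
    emb <- embed_patches(encoder, patches)
    for (k in seq_len(nrow(cells))) tensor[cells[k, 1], cells[k, 2], ] <- emb[k, ]
  }
  structure(list(tensor = tensor, usable_mask = mask), class = "feature_quilt")
}

#' Masked mean pooling of a feature-quilt into a patient feature
#'
#' Arithmetic mean of the usable cells' embeddings; padding cells are
#' excluded. Invariant to any permutation of cell positions.
#'
#' @param fq a [embed_quilt()] feature-quilt.
#' @return length-128 numeric patient image feature.
#' @export
aggregate_quilt <- function(fq) {
  stopifnot(inherits(fq, "feature_quilt"))
  cells <- which(fq$usable_mask, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("no usable cells to pool")
  m <- t(vapply(seq_len(nrow(cells)),
                function(k) fq$tensor[cells[k, 1], cells[k, 2], ], numeric(128L)))
  colMeans(m)
}

#' Mean-pool a set of patch embeddings into a patient feature
#'
#' Equivalent to [aggregate_quilt()] on the corresponding feature-quilt
#' (masked mean pooling is order-invariant), without materializing the quilt.
#'
#' @param embeddings n x 128 matrix of usable-patch embeddings.
#' @return length-128 patient feature.
#' @export
pool_patient_feature <- function(embeddings) {
  if (is.null(dim(embeddings)) || nrow(embeddings) == 0)
    stop("no usable patch embeddings to pool")
  colMeans(embeddings)
}

#' Export per-patch embeddings for external visualization
#'
#' Writes one CSV row per usable patch: patch id, patient id, truth label if
#' known, then the 128 embedding values. Downstream projection/clustering is
#' intentionally out of scope; this is the export surface.
#'
#' @param patch_table data.frame with columns patch_id, patient_id and
#'   optionally truth_label.
#' @param patches list of pixel arrays (or patch lists), same order.
#' @param encoder trained encoder.
#' @param path output CSV path.
#' @return invisibly, the exported data.frame.
#' @export
export_embeddings <- function(patch_table, patches, encoder, path) {
  stopifnot(nrow(patch_table) == length(patches),
            all(c("patch_id", "patient_id") %in% names(patch_table)))
  emb <- embed_patches(encoder, patches)
  colnames(emb) <- sprintf("e%03d", seq_len(ncol(emb)))
  out <- cbind(patch_table, as.data.frame(emb))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
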