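#' Build an enrollment gallery
#'
#' Stores one baseline embedding per patient (the earliest examination),
#' L2-normalized once at enrollment so that matching reduces to a matrix
#' product; the results are identical to unnormalized cosine similarity.
#'
#' @param embeddings `N_g x D` matrix of baseline embeddings.
#' @param patient_ids Character vector, one id per row; unique unless
#'   `multi = TRUE`.
#' @param vendors Optional vendor tag per row.
#' @param multi Allow several enrolled images per patient (scores are then
#'   max-fused per patient by [fuse_gallery_scores()]); off by default —
#'   the standard policy enrolls exactly the earliest baseline image.
#' @return A list of class `reid_gallery`.
#' @export
build_gallery <- function(embeddings, patient_ids, vendors = NULL,
                          multi = FALSE) {
  embeddings <- as.matrix(embeddings)
  if (length(patient_ids) != nrow(embeddings))
    stop("one patient id per gallery row required")
  if (!multi && anyDuplicated(patient_ids))
    stop("gallery keeps exactly one image per patient; duplicated ids: ",
         paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "))
  nz <- sqrt(rowSums(embeddings^2))
  if (any(nz == 0))
    stop("zero embedding vector(s) at gallery row(s): ",
         paste(which(nz == 0), collapse = ", "))
  structure(list(embeddings = embeddings / nz,
                 patient_ids = as.character(patient_ids),
                 vendors = if (is.null(vendors)) rep(NA_character_,
                   nrow(embeddings)) else as.character(vendors)),
            class = "reid_gallery")
}

#' Cosine similarity between query and gallery embeddings
#'
#' `S[i, j] = <q_i, g_j> / (||q_i|| ||g_j||)`, bounded in `[-1, 1]`.
#' Invariant to positive rescaling of either side.
#'
#' @param Q `N_q x D` matrix of query embeddings.
#' @param G `N_g x D` matrix, or a [build_gallery()] object.
#' @return `N_q x N_g` similarity matrix of class `similarity_matrix`.
#' @export
cosine_similarity_matrix <- function(Q, G) {
  Q <- as.matrix(Q)
  Gm <- if (inherits(G, "reid_gallery")) G$embeddings else as.matrix(G)
  nq <- sqrt(rowSums(Q^2)); ng <- sqrt(rowSums(Gm^2))
  if (any(nq == 0))
    stop("zero query vector(s) at row(s): ", paste(which(nq == 0), collapse = ", "))
  if (any(ng == 0))
    stop("zero gallery vector(s) at row(s): ", paste(which(ng == 0), collapse = ", "))
  S <- (Q / nq) %*% t(Gm / ng)
  S <- pmin(pmax(S, -1), 1)
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Rank gallery entries for one query
#'
#' Descending by similarity; ties broken by ascending gallery index (a
#' stable, documented rule).
#'
#' @param S Similarity matrix.
#' @param query_index Row of `S` to rank.
#' @return Integer vector of gallery indices, best match first.
#' @export
rank_gallery <- function(S, query_index) {
  stopifnot(query_index >= 1, query_index <= nrow(S))
  order(-S[query_index, ])     # order() is stable: ties keep ascending index
}

#' Identify the top-k gallery patients for each query
#'
#' @param S Similarity matrix from [cosine_similarity_matrix()].
#' @param gallery A [build_gallery()] object (or a character vector of
#'   gallery patient ids).
#' @param k Number of candidates, `1 <= k <= N_g`.
#' @return List of length `N_q`; each element has `patient_ids` and
#'   `scores` (non-increasing), plus `top_score` for alert thresholding.
#' @export
identify <- function(S, gallery, k = 1) {
  ids <- if (inherits(gallery, "reid_gallery")) gallery$patient_ids
         else as.character(gallery)
  if (k < 1 || k > ncol(S))
    stop("k = ", k, " out of range [1, ", ncol(S), "]")
  lapply(seq_len(nrow(S)), function(i) {
    ord <- rank_gallery(S, i)[seq_len(k)]
    list(patient_ids = ids[ord], scores = S[i, ord], top_score = S[i, ord[1]])
  })
}

#' Fuse multi-image gallery scores per patient
#'
#' For a gallery enrolled with several images per patient
#' (`build_gallery(..., multi = TRUE)`), reduces the query x image
#' similarity matrix to a query x patient matrix by taking each patient's
#' maximum score.
#'
#' @param S Similarity matrix from [cosine_similarity_matrix()].
#' @param patient_ids Gallery patient id per column of `S`.
#' @return List with `values` (`N_q` x n-patients matrix, columns named by
#'   patient) and `patient_ids`.
#' @export
fuse_gallery_scores <- function(S, patient_ids) {
  stopifnot(ncol(S) == length(patient_ids))
  ids <- unique(patient_ids)
  V <- vapply(ids, function(p)
    apply(S[, patient_ids == p, drop = FALSE], 1, max), numeric(nrow(S)))
  V <- matrix(V, nrow = nrow(S), dimnames = list(NULL, ids))
  list(values = V, patient_ids = ids)
}
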