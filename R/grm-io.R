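#' Read and write GRMs in the GCTA binary triplet format
#'
#' The GCTA format stores the lower triangle (including the diagonal) of
#' the GRM row by row as little-endian 4-byte floats in `<prefix>.grm.bin`,
#' the per-pair SNP counts in the same layout in `<prefix>.grm.N.bin`, and
#' the ids as a two-column (family id, individual id) TSV in
#' `<prefix>.grm.id`. Values written here round-trip bit-exactly.
#'
#' @param grm A `kinliab_grm`.
#' @param prefix Path prefix for the three files.
#' @return `write_grm_gcta()` invisibly returns the three paths;
#'   `read_grm_gcta()` returns a `kinliab_grm` (with `n_snps` the maximum
#'   per-pair count).
#' @export
write_grm_gcta <- function(grm, prefix) {
  n <- length(grm$ids)
  lower <- grm$mat[lower.tri(grm$mat, diag = TRUE)]
  # GCTA order is row-major over the lower triangle: (1,1), (2,1), (2,2), ...
  idx <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  vals <- lower[ord]
  nvals <- rep(grm$n_snps, length(vals))
  paths <- paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id"))
  con <- file(paths[1], "wb")
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  close(con)
  con <- file(paths[2], "wb")
  writeBin(as.numeric(nvals), con, size = 4L, endian = "little")
  close(con)
  readr::write_tsv(tibble(fid = grm$ids, iid = grm$ids), paths[3],
                   col_names = FALSE)
  invisible(paths)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  paths <- paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id"))
  ids <- readr::read_tsv(paths[3], col_names = c("fid", "iid"),
                         col_types = "cc", progress = FALSE)
  n <- nrow(ids)
  m <- n * (n + 1) / 2
  vals <- readBin(paths[1], "numeric", n = m, size = 4L, endian = "little")
  nvals <- if (file.exists(paths[2])) {
    readBin(paths[2], "numeric", n = m, size = 4L, endian = "little")
  } else rep(NA_real_, m)
  A <- matrix(0, n, n)
  k <- 1L
  for (i in seq_len(n)) {
    A[i, seq_len(i)] <- vals[k:(k + i - 1L)]
    k <- k + i
  }
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  structure(list(mat = A, ids = ids$iid,
                 n_snps = max(nvals, na.rm = TRUE)),
            class = "kinliab_grm")
}

#' Plain-text GRM interchange
#'
#' Long-format lower-triangle TSV (`id1`, `id2`, `n_snps`, `value`) for
#' debugging and diffing; lossless round trip with [read_grm_text()].
#'
#' @param grm A `kinliab_grm`.
#' @param path Output/input path.
#' @export
write_grm_text <- function(grm, path) {
  n <- length(grm$ids)
  idx <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  out <- tibble(
    id1 = grm$ids[idx[, "row"]],
    id2 = grm$ids[idx[, "col"]],
    n_snps = grm$n_snps,
    value = grm$mat[idx]
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_grm_text
#' @export
read_grm_text <- function(path) {
  d <- readr::read_tsv(path, col_types = "ccdd", progress = FALSE)
  ids <- unique(c(d$id1, d$id2))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(match(d$id1, ids), match(d$id2, ids))] <- d$value
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  structure(list(mat = unname(A), ids = ids, n_snps = max(d$n_snps)),
            class = "kinliab_grm")
}
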