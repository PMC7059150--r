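#' Read an expression matrix from GCT 1.2 or plain TSV
#'
#' GCT files are recognised by their `#1.2` header; anything else is read as
#' TSV with genes as rows and the first column holding gene ids. Duplicate
#' gene ids raise an error; with `counts = TRUE` negative values do too.
#'
#' @param path File path.
#' @param counts Validate the matrix as raw counts (non-negative).
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path, counts = FALSE) {
  first <- readLines(path, n = 1)
  mat <- if (identical(trimws(first), "#1.2")) {
    read_gct(path)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- tab[[1]]
    dups <- unique(ids[duplicated(ids)])
    if (length(dups) > 0) {
      abort(paste0("Duplicated gene id(s): ", paste(dups, collapse = ", ")))
    }
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
    m
  }
  if (counts && any(mat < 0)) {
    abort("Counts matrix contains negative values.")
  }
  mat
}

#' Read a GCT 1.2 expression file
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples; the Description column is kept
#'   as attribute `description`.
#' @export
read_gct <- function(path) {
  lines <- readLines(path, n = 2)
  if (!identical(trimws(lines[1]), "#1.2")) {
    abort("Not a GCT 1.2 file (missing '#1.2' header).")
  }
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  tab <- utils::read.delim(path, skip = 2, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) != dims[1] || ncol(tab) - 2 != dims[2]) {
    abort(paste0("GCT dimension line says ", dims[1], " x ", dims[2],
                 " but body has ", nrow(tab), " x ", ncol(tab) - 2, "."))
  }
  ids <- tab[[1]]
  dups <- unique(ids[duplicated(ids)])
  if (length(dups) > 0) {
    abort(paste0("Duplicated gene id(s): ", paste(dups, collapse = ", ")))
  }
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  attr(m, "description") <- tab[[2]]
  m
}

#' Write an expression matrix as GCT 1.2
#'
#' @param mat Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @param description Optional per-gene description column.
#' @export
write_gct <- function(mat, path, description = NULL) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  desc <- description %||% attr(mat, "description") %||% rownames(mat)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  body <- data.frame(Name = rownames(mat), Description = desc,
                     mat, check.names = FALSE)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_tbl <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE))
}
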