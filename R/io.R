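#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields \code{name},
#' \code{description}, then member genes. Duplicate members within a line
#' are dropped.
#'
#' @param path GMT file path.
#' @return a named list of character vectors with attribute
#'   \code{descriptions} (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 60))
    nm <- fields[1]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", nm)
    sets[[nm]] <- members
    desc[nm] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Read a two-column gene map (gene -> term, or probe -> gene)
#'
#' @param path TSV path with two columns and no header.
#' @return list with \code{forward} (first column -> set of second-column
#'   values) and \code{inverse} (second -> set of first), both named lists of
#'   character vectors. An empty file yields empty maps.
#' @export
read_gene_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(list(forward = list(), inverse = list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("malformed row(s) in ", path, " (expected exactly 2 columns)")
  a <- vapply(parts, `[[`, character(1), 1)
  b <- vapply(parts, `[[`, character(1), 2)
  list(forward = lapply(split(b, a), unique),
       inverse = lapply(split(a, b), unique))
}

#' Read a protein-protein interaction edge list
#'
#' Three tab-separated columns: \code{gene_a}, \code{gene_b}, \code{score}
#' (score optional, defaults to 1.0). The network is undirected; self-loops
#' are dropped and duplicate edges collapsed keeping the maximum score.
#'
#' @param path TSV path, no header.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{score}, endpoints ordered so \code{gene_a < gene_b}.
#' @export
read_ppi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("malformed row(s) in ", path)
  a <- vapply(parts, `[[`, character(1), 1)
  b <- vapply(parts, `[[`, character(1), 2)
  s <- vapply(parts, function(p)
    if (length(p) >= 3) suppressWarnings(as.numeric(p[3])) else 1.0,
    numeric(1))
  if (any(is.na(s))) stop("non-numeric score in ", path)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  best <- tapply(s, key, max)
  ord <- !duplicated(key)
  out <- data.frame(gene_a = lo[ord], gene_b = hi[ord],
                    score = as.numeric(best[key[ord]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a protein-protein interaction edge list
#'
#' @param ppi data.frame as returned by [read_ppi()].
#' @param path output TSV path.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ppi)
}
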