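#' Read / write pool frequency matrices as TSV
#'
#' The on-disk dialect is a tab-separated table with SNP ids in the first
#' column (header `snp`), family ids as the remaining column names and
#' `NA` for missing cells. A depth matrix uses the same layout.
#'
#' @param path file path.
#' @param depth_path optional path of a matching read-depth matrix.
#' @return For `read_frequency_matrix`, a [pool_freq()] object.
#' @export
read_frequency_matrix <- function(path, depth_path = NULL) {
  vals <- read_id_matrix(path)
  depths <- if (!is.null(depth_path)) {
    d <- read_id_matrix(depth_path)
    if (!identical(dim(d), dim(vals)) ||
        !identical(rownames(d), rownames(vals)) ||
        !identical(colnames(d), colnames(vals)))
      stop("depth matrix ids/shape do not match the frequency matrix")
    d
  }
  pool_freq(vals, depths = depths)
}

#' @param x a [pool_freq()] object (or matrix) to write.
#' @rdname read_frequency_matrix
#' @export
write_frequency_matrix <- function(x, path) {
  x <- as_pool_freq(x)
  write_id_matrix(x$values, path, id_col = "snp")
  invisible(path)
}

## internal TSV matrix reader with id checks and line numbers in errors
read_id_matrix <- function(path, id_col = "snp") {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1L]))
    stop("ragged row in ", path, " at line ",
         which(ncols != ncols[1L])[1L])
  header <- fields[[1L]]
  ids <- vapply(fields[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate row id '", ids[duplicated(ids)][1L], "' in ", path,
         " at line ", which(duplicated(ids))[1L] + 1L)
  fam <- header[-1L]
  if (anyDuplicated(fam))
    stop("duplicate column id '", fam[duplicated(fam)][1L], "' in ", path)
  raw <- do.call(rbind, lapply(fields[-1L], function(f) f[-1L]))
  m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  is_na_token <- matrix(raw %in% c("NA", "na", ""), nrow(raw), ncol(raw))
  bad <- which(is.na(m) & !is_na_token, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell '", raw[bad[1L, , drop = FALSE]], "' in ", path,
         " at line ", bad[1L, 1L] + 1L, ", column ", bad[1L, 2L] + 1L)
  dimnames(m) <- list(ids, fam)
  m
}

write_id_matrix <- function(m, path, id_col = "snp") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Read / write a genomic relationship matrix as TSV
#'
#' Square tab-separated matrix with family ids as both header and first
#' column (header `family`).
#'
#' @param path file path.
#' @return For `read_grm`, a numeric family x family matrix.
#' @export
read_grm <- function(path) {
  m <- read_id_matrix(path, id_col = "family")
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("GRM in ", path, " is not square with matching family ids")
  m
}

#' @param G a `pool_grm` or square matrix to write.
#' @rdname read_grm
#' @export
write_grm <- function(G, path) {
  if (inherits(G, "pool_grm")) G <- G$G
  write_id_matrix(G, path, id_col = "family")
  invisible(path)
}

#' Read / write phenotype tables
#'
#' Tab-separated with columns `family`, `rep`, `value` and optionally
#' `trial`, `pop1`, `pop2` (trial block and the two parent-population
#' labels).
#'
#' @param path file path.
#' @return For `read_phenotypes`, a data frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "rep", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("family", "rep")])) {
    d <- df[duplicated(df[c("family", "rep")]), ]
    stop("duplicate (family, rep) pair in ", path, ": family '",
         d$family[1L], "', rep ", d$rep[1L])
  }
  if (!is.numeric(df$value))
    stop("non-numeric 'value' column in ", path)
  df$family <- as.character(df$family)
  df
}

#' @param pheno phenotype data frame to write.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
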