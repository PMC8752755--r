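# Phenotype / covariate tables in the PLINK dialect: whitespace-delimited,
# header with FID and IID, remaining columns numeric.

#' Construct a covariate table
#'
#' A covariate table is a data.frame keyed by (fid, iid) whose remaining
#' columns are numeric. Two named column subsets are carried as attributes:
#' \code{non_genetic} — the covariates the phenotype-prediction network may
#' see (age, sex, batch, ...) — and \code{adjustment} — the full linear
#' adjustment set for association testing, typically the non-genetic columns
#' plus genetic principal components. PC-like columns (names matching
#' \code{^PC[0-9]+$}) may appear in \code{adjustment} but never in
#' \code{non_genetic}: the network must predict phenotype without genetic
#' information.
#'
#' @param df data.frame with \code{fid}, \code{iid} and numeric columns.
#' @param non_genetic character vector of column names (default: all numeric
#'   columns that do not look like PCs).
#' @param adjustment character vector of column names (default: all numeric
#'   columns).
#' @return data.frame of class \code{covariate_table}.
#' @export
covariate_table <- function(df, non_genetic = NULL, adjustment = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("fid", "iid") %in% names(df)))
    dn_stop("covariate_table: need fid and iid columns")
  df$fid <- as.character(df$fid)
  df$iid <- as.character(df$iid)
  key <- dn_key(df$fid, df$iid)
  if (anyDuplicated(key))
    dn_stop("covariate_table: duplicated sample key %s",
            key[duplicated(key)][1])
  value_cols <- setdiff(names(df), c("fid", "iid"))
  pc_like <- grepl("^PC[0-9]+$", value_cols)
  non_genetic <- non_genetic %||% value_cols[!pc_like]
  adjustment <- adjustment %||% value_cols
  for (set in list(non_genetic, adjustment))
    if (!all(set %in% value_cols))
      dn_stop("covariate_table: unknown column(s): %s",
              paste(setdiff(set, value_cols), collapse = ", "))
  if (any(grepl("^PC[0-9]+$", non_genetic)))
    dn_stop("covariate_table: PC-like columns cannot be non_genetic")
  structure(df, non_genetic = non_genetic, adjustment = adjustment,
            class = c("covariate_table", "data.frame"))
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("covariate_table: %d individuals, columns: %s\n", nrow(x),
              paste(setdiff(names(x), c("fid", "iid")), collapse = ", ")))
  cat(sprintf("  non_genetic: %s\n",
              paste(attr(x, "non_genetic"), collapse = ", ")))
  cat(sprintf("  adjustment:  %s\n",
              paste(attr(x, "adjustment"), collapse = ", ")))
  invisible(x)
}

#' Read a phenotype or covariate table
#'
#' Whitespace-delimited with a header naming FID and IID; remaining columns
#' are parsed as numeric with the given NA codes. Lines starting with
#' \code{#} are ignored. A phenotype file must have exactly one value column.
#'
#' @param path file path.
#' @param kind "covariate" or "phenotype".
#' @param na character vector of NA codes.
#' @return for kind = "covariate", a \code{\link{covariate_table}};
#'   for kind = "phenotype", a data.frame (fid, iid, value column) of class
#'   \code{phenotype_table}.
#' @export
read_table <- function(path, kind = c("covariate", "phenotype"),
                       na = c("NA", "-9")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) dn_stop("read_table: missing file %s", path)
  lines <- dn_read_lines_nocomment(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) dn_stop("read_table: %s is empty", path)
  header <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (!all(c("FID", "IID") %in% header))
    dn_stop("read_table: %s header must contain FID and IID", path)
  body <- strsplit(trimws(lines[-1]), "[ \t]+")
  nc <- lengths(body)
  if (any(nc != length(header)))
    dn_stop("read_table: %s data row %d has %d fields, expected %d",
            path, which(nc != length(header))[1],
            nc[nc != length(header)][1], length(header))
  tab <- do.call(rbind, body)
  colnames(tab) <- header
  out <- data.frame(fid = tab[, "FID"], iid = tab[, "IID"],
                    stringsAsFactors = FALSE)
  for (col in setdiff(header, c("FID", "IID"))) {
    raw <- tab[, col]
    raw[raw %in% na] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad))
      dn_stop("read_table: %s non-numeric value '%s' at data row %d column %s",
              path, raw[bad[1]], bad[1], col)
    out[[col]] <- num
  }
  if (kind == "phenotype") {
    if (ncol(out) != 3)
      dn_stop("read_table: phenotype file %s must have exactly one value column",
              path)
    class(out) <- c("phenotype_table", "data.frame")
    out
  } else {
    covariate_table(out)
  }
}

#' Write a phenotype or covariate table in the PLINK dialect
#' @param df data.frame with fid, iid and numeric columns (covariate_table and
#'   phenotype_table objects included).
#' @param path output path.
#' @param stamp optional named list echoed as `## key=value` header comments.
#' @return invisibly, the path.
#' @export
write_table <- function(df, path, stamp = NULL) {
  value_cols <- setdiff(names(df), c("fid", "iid"))
  header <- paste(c("FID", "IID", value_cols), collapse = " ")
  vals <- as.matrix(as.data.frame(df)[, value_cols, drop = FALSE])
  body <- apply(cbind(df$fid, df$iid,
                      ifelse(is.na(vals), "NA", format(vals, digits = 17,
                                                       trim = TRUE,
                                                       scientific = FALSE))),
                1, paste, collapse = " ")
  lines <- c(if (!is.null(stamp)) dn_stamp(stamp), header, body)
  writeLines(lines, path)
  invisible(path)
}

#' Extract a named phenotype vector keyed by sample
#' @param pheno phenotype_table (or data.frame with fid, iid and one value
#'   column), or an already-named numeric vector (returned unchanged).
#' @return numeric vector named by "fid:iid" keys.
#' @export
phenotype_vector <- function(pheno) {
  if (is.numeric(pheno) && !is.null(names(pheno))) return(pheno)
  value_cols <- setdiff(names(pheno), c("fid", "iid"))
  if (length(value_cols) != 1)
    dn_stop("phenotype_vector: expected exactly one value column")
  stats::setNames(pheno[[value_cols]], dn_key(pheno$fid, pheno$iid))
}
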