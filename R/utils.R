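# helpers shared across modules

#' Canonical per-individual key used for all joins
#' @param fid,iid family and individual identifiers.
#' @return character vector "fid:iid".
#' @export
dn_key <- function(fid, iid) paste(fid, iid, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

dn_stop <- function(...) stop(sprintf(...), call. = FALSE)

# Seeded evaluation that leaves the caller's RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# "# key=value" header lines stamped into text outputs so every run is
# reproducible from its own files
dn_stamp <- function(params) {
  vals <- vapply(params, function(v) paste(format(v), collapse = ","),
                 character(1))
  c(sprintf("## deepnull %s", as.character(utils::packageVersion("deepnull"))),
    sprintf("## %s=%s", names(params), vals))
}

dn_read_lines_nocomment <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#")]
}
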