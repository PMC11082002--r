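# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# `seed = NULL` means "use the current RNG stream".
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

# Provenance header written at the top of every TSV the package emits.
# Deliberately timestamp-free so reruns with identical seeds are byte-identical.
provenance_header <- function(what, seed = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("coreshift")),
                  error = function(e) "dev")
  h <- sprintf("# coreshift %s | %s", ver, what)
  if (!is.null(seed)) h <- paste0(h, sprintf(" | seed=%d", as.integer(seed)))
  h
}

write_tsv_prov <- function(df, path, what, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(what, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE, quote = "")
}
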