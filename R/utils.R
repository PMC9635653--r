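# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package funnel
# through this so a single seed fixes every output byte.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

# Write a data.frame as plain TSV (the package's tabular interchange format).
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

# Split "Fg,Ps" -> c("Fg","Ps"); "" -> character(0)
split_csv_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}

join_csv_field <- function(x) paste(x, collapse = ",")
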