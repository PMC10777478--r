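# shared internal helpers

# canonical "i|j" key with i < j lexicographically (C locale so ordering is
# platform independent)
pair_key <- function(i, j) {
  lt <- compare_lt(i, j)
  lo <- ifelse(lt, i, j)
  hi <- ifelse(lt, j, i)
  paste(lo, hi, sep = "|")
}

# locale-stable lexicographic comparison
compare_lt <- function(a, b) {
  withr::with_locale(c(LC_COLLATE = "C"), a < b)
}

# locale-stable sort, used everywhere column / node order must be
# deterministic across machines
lex_sort <- function(x) {
  withr::with_locale(c(LC_COLLATE = "C"), sort(x, method = "radix"))
}

lex_order <- function(...) {
  withr::with_locale(c(LC_COLLATE = "C"), order(..., method = "radix"))
}

# write a file atomically: write to a sibling temp file, then rename
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

`%||%` <- rlang::`%||%`
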