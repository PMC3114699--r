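# shared internal helpers

# truncate (not round) to 2 decimals; used for printed per-gene rates
trunc2 <- function(x) trunc(x * 100) / 100

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a short class so tests can assert on the error kind
stop_cls <- function(class, ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# write a named list as pretty-printed JSON, deterministically
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
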