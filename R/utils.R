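# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers (and the CLI) can distinguish user/config
# errors from internal failures.
gtb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gtb_error", "error")))
}

gtb_io_error        <- function(msg) gtb_stop(msg, "gtb_io_error")
gtb_format_error    <- function(msg) gtb_stop(msg, "gtb_format_error")
gtb_shape_error     <- function(msg) gtb_stop(msg, "gtb_shape_error")
gtb_selection_error <- function(msg) gtb_stop(msg, "gtb_selection_error")
gtb_config_error    <- function(msg) gtb_stop(msg, "gtb_config_error")
gtb_degeneracy_error<- function(msg) gtb_stop(msg, "gtb_degeneracy_error")
gtb_argument_error  <- function(msg) gtb_stop(msg, "gtb_argument_error")
gtb_fit_error       <- function(msg) gtb_stop(msg, "gtb_fit_error")
gtb_spec_error      <- function(msg) gtb_stop(msg, "gtb_spec_error")

# Normalise a residue selection into a sorted integer vector of residue
# numbers. Accepts an integer vector, a single c(lo, hi) range, a list of
# ranges, or an n x 2 matrix of ranges.
resolve_ranges <- function(x) {
  if (is.null(x) || length(x) == 0) {
    gtb_selection_error("selection is empty")
  }
  if (is.matrix(x)) x <- split(x, seq_len(nrow(x)))
  if (is.list(x)) {
    out <- unlist(lapply(x, function(r) {
      if (length(r) == 1) return(as.integer(r))
      if (length(r) != 2 || r[2] < r[1]) {
        gtb_selection_error("ranges must be c(lo, hi) with hi >= lo")
      }
      seq.int(as.integer(r[1]), as.integer(r[2]))
    }))
    return(sort(unique(out)))
  }
  sort(unique(as.integer(x)))
}

# Trapezoid integral on a uniform or non-uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Run code with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "fg")
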