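#' Ground-truth record for a synthetic fixture
#'
#' Every generated fixture carries exactly one of these: the fixture id, the
#' seed actually used, and a flat name -> numeric value map of the generator's
#' true parameters (true channel signals, polymer fractions, invasion
#' fractions, effect shapes encoded as documented by each generator).
#'
#' @param fixture_id character id of the fixture.
#' @param seed integer seed used for generation (recorded verbatim).
#' @param values named numeric vector of true parameter values.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(fixture_id, seed, values) {
  stopifnot(is.character(fixture_id), length(fixture_id) == 1L)
  if (is.list(values)) values <- unlist(values)
  stopifnot(is.numeric(values), !is.null(names(values)), all(names(values) != ""))
  structure(list(fixture_id = fixture_id, seed = as.integer(seed),
                 values = values),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (seed %d)\n", x$fixture_id, x$seed))
  print(x$values)
  invisible(x)
}

#' @export
as.data.frame.ground_truth <- function(x, ...) {
  data.frame(fixture_id = x$fixture_id, seed = x$seed,
             parameter = names(x$values), value = unname(x$values),
             stringsAsFactors = FALSE)
}

#' Write ground-truth records to CSV
#'
#' Long format (fixture_id, seed, parameter, value); full double precision so
#' records round-trip unchanged through [read_ground_truth()].
#'
#' @param truths a `ground_truth` or list of them.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(truths, path) {
  if (inherits(truths, "ground_truth")) truths <- list(truths)
  df <- do.call(rbind, lapply(truths, as.data.frame))
  df$value <- sprintf("%.17g", df$value)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read ground-truth records written by [write_ground_truth()]
#' @param path CSV path.
#' @return named list of `ground_truth` objects keyed by fixture id.
#' @export
read_ground_truth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(fixture_id = "character", parameter = "character",
                                value = "character"))
  out <- lapply(split(df, df$fixture_id), function(d) {
    ground_truth(d$fixture_id[1], d$seed[1],
                 stats::setNames(as.numeric(d$value), d$parameter))
  })
  out[unique(df$fixture_id)]
}
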