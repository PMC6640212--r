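#' Write a tensor to the two-line text interchange format
#'
#' The format has exactly two lines: the first holds the comma-separated
#' shape integers, the second the comma-separated values in row-major order
#' (last axis varying fastest). Reals are written with enough digits for a
#' bit-exact round trip; missing values serialize as \code{NA}.
#'
#' @param tensor a numeric array, matrix or vector.
#' @param destination path of the file to write.
#' @return the destination path, invisibly.
#' @export
tensor_to_text <- function(tensor, destination) {
  d <- dim(tensor)
  if (is.null(d)) d <- length(tensor)
  v <- if (length(d) > 1L)
    as.vector(aperm(tensor, rev(seq_along(d)))) else as.vector(tensor)
  fmt <- function(x) {
    out <- vapply(x, function(e) {
      if (is.na(e)) "NA"
      else if (is.integer(e) || e == floor(e)) format(e, scientific = FALSE)
      else sprintf("%.17g", e)
    }, character(1))
    out
  }
  lines <- c(paste(d, collapse = ","), paste(fmt(v), collapse = ","))
  writeLines(lines, destination)
  invisible(destination)
}

#' Read a tensor from the two-line text interchange format
#'
#' The inverse of [tensor_to_text()]. Malformed files are rejected with a
#' diagnosis naming the offending line.
#'
#' @param source path of the file to read.
#' @return a numeric array with the shape declared on line 1.
#' @export
text_to_tensor <- function(source) {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) < 2L)
    stop("format error: expected 2 lines (shape, values), found ",
         length(lines))
  shape <- suppressWarnings(as.integer(strsplit(lines[1L], ",")[[1L]]))
  if (length(shape) == 0L || anyNA(shape) || any(shape < 0L))
    stop("format error on line 1: shape must be comma-separated ",
         "non-negative integers, got \"", lines[1L], "\"")
  raw_vals <- strsplit(lines[2L], ",")[[1L]]
  vals <- suppressWarnings(as.numeric(raw_vals))
  bad <- which(is.na(vals) & trimws(raw_vals) != "NA")
  if (length(bad) > 0L)
    stop("format error on line 2: non-numeric value \"",
         raw_vals[bad[1L]], "\" at position ", bad[1L])
  if (length(vals) != prod(shape))
    stop("format error on line 2: shape (", lines[1L], ") implies ",
         prod(shape), " values but line 2 holds ", length(vals))
  if (length(shape) == 1L) return(array(vals, dim = shape))
  aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
}

#' Save network weights to a self-describing text checkpoint
#'
#' Writes every convolutional stage's weight tensor in the two-line text
#' tensor format, preceded by a version-tagged header, so a trained network
#' can be restored into an identically-shaped [network_spec()].
#'
#' @param net a [network_spec()].
#' @param destination file path.
#' @return the destination path, invisibly.
#' @export
save_weights <- function(net, destination) {
  stopifnot(inherits(net, "network_spec"))
  con <- file(destination, "w")
  on.exit(close(con))
  writeLines(c("spikewave-checkpoint 1",
               paste("stages", length(net$stages))), con)
  for (i in seq_along(net$stages)) {
    w <- net$stages[[i]]$conv$weights
    d <- dim(w)
    v <- as.vector(aperm(w, rev(seq_along(d))))
    writeLines(c(paste("layer", i),
                 paste(d, collapse = ","),
                 paste(sprintf("%.17g", v), collapse = ",")), con)
  }
  invisible(destination)
}

#' Restore network weights from a text checkpoint
#'
#' @param net a [network_spec()] with the same architecture the checkpoint
#'   was saved from.
#' @param source file path written by [save_weights()].
#' @return the network with restored weights.
#' @export
load_weights <- function(net, source) {
  stopifnot(inherits(net, "network_spec"))
  lines <- readLines(source, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1L], "spikewave-checkpoint"))
    stop("not a spikewave checkpoint file")
  n <- as.integer(strsplit(lines[2L], " ")[[1L]][2L])
  if (n != length(net$stages))
    stop("checkpoint holds ", n, " stages but the network has ",
         length(net$stages))
  pos <- 3L
  for (i in seq_len(n)) {
    shape <- as.integer(strsplit(lines[pos + 1L], ",")[[1L]])
    vals <- as.numeric(strsplit(lines[pos + 2L], ",")[[1L]])
    if (length(vals) != prod(shape))
      stop("corrupt checkpoint: stage ", i, " value count mismatch")
    w <- aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
    if (!identical(dim(w), dim(net$stages[[i]]$conv$weights)))
      stop("checkpoint stage ", i, " shape does not match the network")
    net$stages[[i]]$conv$weights <- w
    pos <- pos + 3L
  }
  net
}
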