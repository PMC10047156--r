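#' Read and write networks as JSON
#'
#' The container is a small documented JSON object:
#' \preformatted{
#' {
#'   "format": "relaytrace-network",
#'   "version": 1,
#'   "layer_sizes": [16, 8, 4],
#'   "layers": [
#'     {"weights": [[...], ...], "biases": [...]},   # row-major matrices
#'     {"weights": [[...], ...], "biases": [...]}
#'   ],
#'   "target_class": 3          # optional, one-versus-rest sub-networks
#' }
#' }
#' Numbers are written at full precision so a write/read cycle reproduces the
#' network exactly.
#'
#' @param net A [relay_network()].
#' @param path File path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a `relay_network`.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "relay_network"))
  obj <- list(
    format = "relaytrace-network",
    version = 1L,
    layer_sizes = layer_sizes(net),
    layers = lapply(1:2, function(l) {
      list(weights = unname(net$weights[[l]]), biases = net$biases[[l]])
    })
  )
  tc <- attr(net, "target_class")
  if (!is.null(tc)) obj$target_class <- tc
  rm <- attr(net, "relay_map")
  if (!is.null(rm)) obj$relay_map <- rm
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "relaytrace-network")) {
    stop("not a relaytrace network file")
  }
  weights <- list(obj$layers$weights[[1L]], obj$layers$weights[[2L]])
  biases <- list(obj$layers$biases[[1L]], obj$layers$biases[[2L]])
  # a 1-column second layer arrives as a plain vector
  weights <- lapply(seq_along(weights), function(l) {
    w <- weights[[l]]
    if (is.null(dim(w))) w <- matrix(w, ncol = 1L)
    w
  })
  net <- relay_network(weights, biases)
  if (!is.null(obj$target_class)) {
    attr(net, "target_class") <- as.integer(obj$target_class)
  }
  if (!is.null(obj$relay_map)) {
    attr(net, "relay_map") <- lapply(obj$relay_map, as.integer)
  }
  net
}
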