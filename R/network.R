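#' Build the raw symmetric container-flow matrix
#'
#' Accumulates an edge list of directed annual container volumes into a
#' symmetric flow matrix over a fixed port roster. Flows in either
#' direction between two ports are combined (by default summed, the
#' "bidirectionally exchanged" convention); self-flows are dropped so the
#' diagonal is zero, the standard convention for CAR weight matrices.
#'
#' @param edges data.frame with columns \code{origin}, \code{destination},
#'   \code{volume} (containers/year, TEU, nonnegative). Duplicate
#'   origin-destination pairs are allowed and accumulate.
#' @param roster character vector of port ids; fixes the ordering of all
#'   downstream matrices and vectors.
#' @param combine how the two directed volumes between a pair are
#'   combined: \code{"sum"} (default) or \code{"max"}.
#' @return an N x N symmetric numeric matrix with zero diagonal, in
#'   roster order, with \code{dimnames} set to the roster.
#' @export
build_flow_matrix <- function(edges, roster, combine = c("sum", "max")) {
  combine <- match.arg(combine)
  stopifnot(is.data.frame(edges))
  need <- c("origin", "destination", "volume")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0L)
    stop("edge list is missing column(s): ", paste(miss, collapse = ", "))
  roster <- as.character(roster)
  if (anyDuplicated(roster))
    stop("port roster contains duplicated ids")
  N <- length(roster)
  o <- as.character(edges$origin)
  d <- as.character(edges$destination)
  v <- as.numeric(edges$volume)
  unknown <- setdiff(unique(c(o, d)), roster)
  if (length(unknown) > 0L)
    stop("edge endpoint(s) not in port roster: ",
         paste(unknown, collapse = ", "))
  if (any(!is.finite(v)) || any(v < 0))
    stop("edge volumes must be finite and nonnegative")
  io <- match(o, roster)
  id <- match(d, roster)
  raw <- matrix(0, N, N, dimnames = list(roster, roster))
  if (combine == "sum") {
    for (e in seq_along(v)) {
      if (io[e] == id[e]) next  # self-flow: zero diagonal by convention
      raw[io[e], id[e]] <- raw[io[e], id[e]] + v[e]
    }
    raw <- raw + t(raw)
  } else {
    dir1 <- matrix(0, N, N)
    for (e in seq_along(v)) {
      if (io[e] == id[e]) next
      dir1[io[e], id[e]] <- dir1[io[e], id[e]] + v[e]
    }
    raw <- pmax(dir1, t(dir1))
    dimnames(raw) <- list(roster, roster)
  }
  raw
}

#' Scale a flow matrix to a CAR weight matrix with maximum 1
#'
#' The flow matrix has a much wider range than the binary adjacency
#' usually used with CAR priors, and the scale of W affects the fit. The
#' matrix is therefore rescaled by \code{alpha_scale = 1/max(raw)} so its
#' largest entry is exactly 1; this rescaling preserves positive
#' definiteness of the Leroux precision built from it.
#'
#' @param raw symmetric nonnegative matrix with zero diagonal (from
#'   \code{\link{build_flow_matrix}}).
#' @return an object of class \code{port_network}: list with
#'   \code{ports}, \code{W}, \code{alpha_scale} (1/containers) and
#'   \code{row_sums}.
#' @export
scale_weights <- function(raw) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  if (max(abs(raw - t(raw))) > 1e-8 * max(1, max(abs(raw))))
    stop("flow matrix must be symmetric")
  if (any(diag(raw) != 0))
    stop("flow matrix must have a zero diagonal")
  if (any(raw < 0))
    stop("flow matrix entries must be nonnegative")
  m <- max(raw)
  if (m == 0)
    stop("network has no flows; CAR undefined")
  alpha <- 1 / m
  W <- alpha * raw
  ports <- rownames(raw)
  if (is.null(ports)) ports <- as.character(seq_len(nrow(raw)))
  rs <- rowSums(W)
  isolated <- ports[rs == 0]
  if (length(isolated) > 0L)
    warning("isolated port(s) with zero flow: ",
            paste(isolated, collapse = ", "))
  structure(
    list(ports = ports, W = W, alpha_scale = alpha, row_sums = rs),
    class = "port_network"
  )
}

#' Construct a port network from an edge list in one step
#'
#' @inheritParams build_flow_matrix
#' @inheritParams scale_weights
#' @return a \code{port_network} (see \code{\link{scale_weights}}).
#' @examples
#' edges <- data.frame(origin = c("A", "B", "B"),
#'                     destination = c("B", "A", "C"),
#'                     volume = c(10, 5, 1))
#' net <- port_network(edges, roster = c("A", "B", "C"))
#' net$W
#' @export
port_network <- function(edges, roster, combine = "sum") {
  scale_weights(build_flow_matrix(edges, roster, combine = combine))
}

#' @export
print.port_network <- function(x, ...) {
  cat("Port flow network:", length(x$ports), "ports\n")
  cat("  max weight 1 (alpha_scale =", format(x$alpha_scale), ")\n")
  cat("  nonzero weight fraction:",
      format(mean(x$W[upper.tri(x$W)] > 0), digits = 3), "\n")
  invisible(x)
}

as_port_network <- function(x) {
  if (inherits(x, "port_network")) return(x)
  if (is.matrix(x)) return(scale_weights(x))
  stop("cannot interpret object as a port network")
}
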