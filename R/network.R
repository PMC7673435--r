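#' Build a pre-stressed hexagonal spring network
#'
#' Constructs a honeycomb patch of `rows` x `cols` hexagonal cells whose edges
#' are identical Hookean springs. Springs are pre-stressed: each is built with
#' rest length `spacing * (1 - prestrain)`, shorter than its geometric length
#' `spacing`, so the resting lattice carries tension as soft tissues do.
#' Nodes on the outer ring (those belonging to fewer than three hexagonal
#' cells) are flagged as boundary nodes and are held fixed during
#' equilibration; every interior node joins exactly three springs.
#'
#' The exact node/spring count depends on the patch shape; a 10 x 10 offset
#' patch (the package default for experiments) has 240 nodes and 339 springs.
#'
#' @param rows,cols Number of hexagonal cells in each direction, >= 1.
#' @param spacing Hexagon side length (dimensionless length unit).
#' @param prestrain Fractional pre-stress in (0, 1); rest length is
#'   `spacing * (1 - prestrain)`.
#' @param k_baseline Baseline spring constant assigned to every spring; also
#'   stored as `k_star_reference`, the homeostatic reference against which
#'   injury and halo are measured.
#' @return An object of class `hex_network`: a list with tibbles `nodes`
#'   (`id`, `x`, `y`, `boundary`) and `springs` (`id`, `from`, `to`,
#'   `stiffness`, `rest_length`), adjacency matrices used by the simulator,
#'   and scalars `k_star_reference`, `spacing`, `prestrain`, `n_hexagons`.
#' @examples
#' net <- build_hex_network(1, 1)        # a single hexagon: 6 nodes, 6 springs
#' net <- build_hex_network(4, 4, k_baseline = 1.022612)
#' @export
build_hex_network <- function(rows, cols, spacing = 1, prestrain = 0.1,
                              k_baseline = 1) {
  stopifnot(rows >= 1, cols >= 1, rows == round(rows), cols == round(cols),
            spacing > 0, prestrain > 0, prestrain < 1, k_baseline > 0)
  s <- spacing
  # flat-top hexagons on an offset grid; vertices at angles 0, 60, ..., 300
  ang <- (0:5) * pi / 3
  vx <- s * cos(ang); vy <- s * sin(ang)
  key <- function(x, y) paste(round(x / s, 6), round(y / s, 6))
  node_x <- numeric(0); node_y <- numeric(0)
  node_id <- new.env(hash = TRUE, parent = emptyenv())
  hex_count <- integer(0)  # hexagon membership per node
  edges <- list(); ei <- 0L
  for (i in seq_len(cols)) {
    cx <- 1.5 * s * (i - 1)
    for (j in seq_len(rows)) {
      cy <- sqrt(3) * s * ((j - 1) + 0.5 * ((i - 1) %% 2))
      px <- cx + vx; py <- cy + vy
      ids <- integer(6)
      for (v in 1:6) {
        kk <- key(px[v], py[v])
        id <- node_id[[kk]]
        if (is.null(id)) {
          node_x <- c(node_x, px[v]); node_y <- c(node_y, py[v])
          id <- length(node_x)
          node_id[[kk]] <- id
          hex_count[id] <- 0L
        }
        ids[v] <- id
        hex_count[id] <- hex_count[id] + 1L
      }
      for (v in 1:6) {
        a <- ids[v]; b <- ids[if (v == 6) 1L else v + 1L]
        ei <- ei + 1L
        edges[[ei]] <- c(min(a, b), max(a, b))
      }
    }
  }
  emat <- unique(do.call(rbind, edges))
  # canonical node order: by (y, x); remap everything
  ord <- order(round(node_y, 9), round(node_x, 9))
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  node_x <- node_x[ord]; node_y <- node_y[ord]; hex_count <- hex_count[ord]
  emat <- cbind(remap[emat[, 1L]], remap[emat[, 2L]])
  emat <- t(apply(emat, 1L, sort))
  emat <- emat[order(emat[, 1L], emat[, 2L]), , drop = FALSE]

  n_nodes <- length(node_x); n_springs <- nrow(emat)
  # center coordinates on the node centroid
  node_x <- node_x - mean(node_x); node_y <- node_y - mean(node_y)
  nodes <- tibble::tibble(id = seq_len(n_nodes), x = node_x, y = node_y,
                          boundary = hex_count < 3L)
  springs <- tibble::tibble(id = seq_len(n_springs),
                            from = emat[, 1L], to = emat[, 2L],
                            stiffness = k_baseline,
                            rest_length = s * (1 - prestrain))
  net <- structure(list(nodes = nodes, springs = springs,
                        k_star_reference = k_baseline,
                        spacing = s, prestrain = prestrain,
                        n_hexagons = rows * cols),
                   class = "hex_network")
  rebuild_adjacency(net)
}

# incidence matrices for the vectorized walker: slot j of node v holds the
# j-th incident spring / neighbor; empty slots point at the padding index
# (n_springs + 1, stiffness 0) so they can never be sampled.
rebuild_adjacency <- function(net) {
  n_nodes <- nrow(net$nodes); n_springs <- nrow(net$springs)
  deg <- integer(n_nodes)
  maxdeg <- 3L
  inc_spr <- matrix(n_springs + 1L, n_nodes, maxdeg)
  inc_nod <- matrix(1L, n_nodes, maxdeg)
  from <- net$springs$from; to <- net$springs$to
  for (s in seq_len(n_springs)) {
    for (v in c(from[s], to[s])) {
      deg[v] <- deg[v] + 1L
      if (deg[v] > maxdeg) stop("node degree exceeds 3; not a honeycomb patch")
      inc_spr[v, deg[v]] <- s
      inc_nod[v, deg[v]] <- if (v == from[s]) to[s] else from[s]
    }
  }
  net$inc_springs <- inc_spr
  net$inc_nodes <- inc_nod
  net$degree <- deg
  net
}

#' @export
print.hex_network <- function(x, ...) {
  cat("<hex_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$boundary), " boundary), ", nrow(x$springs),
      " springs, k* ref = ", format(x$k_star_reference), "\n", sep = "")
  invisible(x)
}

#' @rdname network_tables
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "hex_network"))
  net$nodes
}

#' Network component tables
#'
#' Accessors returning the node and spring tables of a [build_hex_network()]
#' object as tibbles.
#'
#' @param net A `hex_network`.
#' @return A tibble of nodes or springs.
#' @name network_tables
#' @export
network_springs <- function(net) {
  stopifnot(inherits(net, "hex_network"))
  net$springs
}

#' Identify the central spring
#'
#' Deterministically returns the id of the spring whose midpoint lies nearest
#' the centroid of all node positions; ties are broken by the lowest spring
#' index. Used as the injury site.
#'
#' @param net A `hex_network`.
#' @return A single spring id (integer).
#' @export
central_spring <- function(net) {
  stopifnot(inherits(net, "hex_network"))
  nd <- net$nodes
  cx <- mean(nd$x); cy <- mean(nd$y)
  mx <- (nd$x[net$springs$from] + nd$x[net$springs$to]) / 2
  my <- (nd$y[net$springs$from] + nd$y[net$springs$to]) / 2
  d2 <- round((mx - cx)^2 + (my - cy)^2, 9)
  which.min(d2)[1L]  # which.min takes the first (lowest index) on ties
}

#' Apply a focal injury
#'
#' Sets the stiffness of one spring to `factor * k_star_reference`, modelling
#' a localized scar (factor 2 is the default injury of the healing
#' experiments). All other springs are untouched.
#'
#' @param net A `hex_network`.
#' @param spring Spring id; defaults to [central_spring()].
#' @param factor Multiplier applied to the reference stiffness, > 0.
#' @return The modified network.
#' @export
apply_injury <- function(net, spring = central_spring(net), factor = 2) {
  stopifnot(inherits(net, "hex_network"), factor > 0)
  if (!spring %in% net$springs$id) {
    stop("unknown spring id: ", spring, call. = FALSE)
  }
  net$springs$stiffness[net$springs$id == spring] <-
    factor * net$k_star_reference
  net
}

#' Spring stiffness summary
#'
#' @param net A `hex_network`.
#' @return A one-row tibble with `mean` and population `sd` (divisor n) of
#'   the spring stiffnesses.
#' @export
spring_stats <- function(net) {
  stopifnot(inherits(net, "hex_network"))
  k <- net$springs$stiffness
  tibble::tibble(mean = mean(k), sd = sqrt(mean((k - mean(k))^2)))
}

#' Halo of stiffened springs
#'
#' The halo is the set of springs whose stiffness exceeds the homeostatic
#' reference by more than the threshold fraction (default 0.1%, i.e.
#' stiffness > 1.001 * k*). During injury resolution the halo first grows
#' around the injury site, then shrinks back to the empty set.
#'
#' @param net A `hex_network`.
#' @param threshold Multiplicative threshold on `k_star_reference`
#'   (default 1.001).
#' @return Integer vector of spring ids in the halo.
#' @seealso [halo_size()]
#' @export
halo <- function(net, threshold = 1.001) {
  stopifnot(inherits(net, "hex_network"), threshold > 0)
  net$springs$id[net$springs$stiffness > threshold * net$k_star_reference]
}

#' @rdname halo
#' @export
halo_size <- function(net, threshold = 1.001) length(halo(net, threshold))

#' Serialize / restore a network as JSON
#'
#' Writes the node and spring tables (positions, boundary flags, endpoints,
#' stiffnesses, rest lengths) plus the reference stiffness to a JSON file, and
#' reads such a file back into a `hex_network`.
#'
#' @param net A `hex_network`.
#' @param path File path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a `hex_network`.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "hex_network"))
  obj <- list(nodes = net$nodes, springs = net$springs,
              k_star_reference = net$k_star_reference,
              spacing = net$spacing, prestrain = net$prestrain,
              n_hexagons = net$n_hexagons)
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(list(nodes = tibble::as_tibble(obj$nodes),
                        springs = tibble::as_tibble(obj$springs),
                        k_star_reference = obj$k_star_reference,
                        spacing = obj$spacing, prestrain = obj$prestrain,
                        n_hexagons = obj$n_hexagons),
                   class = "hex_network")
  net$nodes$id <- as.integer(net$nodes$id)
  net$springs$id <- as.integer(net$springs$id)
  net$springs$from <- as.integer(net$springs$from)
  net$springs$to <- as.integer(net$springs$to)
  rebuild_adjacency(net)
}
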