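# Projection of the (linearised or quadratic) deviation dynamics onto a
# chosen subnetwork: observable bookkeeping, rate matrix, memory functions,
# memory amplitudes and channel decomposition.

#' Observable index for a subnetwork/bulk partition
#'
#' Enumerates the observables of the projected description: all linear
#' deviations, then (at quadratic order) all canonical products
#' \eqn{\delta x_j \delta x_k} with j <= k. The subnetwork block S contains
#' the linear subnetwork deviations and products of two subnetwork species;
#' every observable touching a bulk species belongs to the bulk block B.
#'
#' @param species character vector of dynamic species names.
#' @param subnetwork character vector (subset of \code{species}).
#' @param order \code{"linear"} or \code{"quadratic"}.
#' @return list with the observable table (\code{obs}: name, kind, j, k,
#'   block), index vectors \code{S} and \code{B}, and the partition.
#' @export
observable_index <- function(species, subnetwork,
                             order = c("linear", "quadratic")) {
  order <- match.arg(order)
  stopifnot(length(subnetwork) >= 1, all(subnetwork %in% species))
  n <- length(species)
  sub <- species %in% subnetwork
  obs <- data.frame(name = species, kind = "linear",
                    j = seq_len(n), k = NA_integer_,
                    block = ifelse(sub, "S", "B"),
                    stringsAsFactors = FALSE)
  if (order == "quadratic") {
    pr <- pair_index(n)
    qobs <- data.frame(
      name = paste0("(", species[pr[, 1]], ",", species[pr[, 2]], ")"),
      kind = "quadratic", j = pr[, 1], k = pr[, 2],
      block = ifelse(sub[pr[, 1]] & sub[pr[, 2]], "S", "B"),
      stringsAsFactors = FALSE)
    obs <- rbind(obs, qobs)
  }
  list(obs = obs, S = which(obs$block == "S"), B = which(obs$block == "B"),
       species = species, subnetwork = subnetwork,
       bulk = setdiff(species, subnetwork), order = order)
}

#' Extended dynamical matrix over linear and quadratic observables
#'
#' Builds the matrix governing \eqn{\partial_t z^T = z^T L_{ext}} for the
#' observable vector z of all deviations and canonical products. The
#' quadratic-to-quadratic block follows from the product rule applied to the
#' linear dynamics; cubic terms generated by the quadratic coefficients are
#' discarded (second-order truncation). The linear-to-quadratic block is
#' zero.
#'
#' @param expansion a \code{grn_taylor} (needs \code{Q} at quadratic order).
#' @param order \code{"linear"} or \code{"quadratic"}.
#' @return square matrix over the observables, row = source orientation.
#' @export
build_extended_L <- function(expansion, order = c("linear", "quadratic")) {
  order <- match.arg(order)
  L <- expansion$L
  if (order == "linear") return(L)
  if (is.null(expansion$Q))
    stop("quadratic order requested but the expansion has no Q; ",
         "use quadratic_expansion()")
  n <- nrow(L)
  pr <- pair_index(n)
  npair <- nrow(pr)
  pidx <- matrix(0L, n, n)
  for (p in seq_len(npair)) {
    pidx[pr[p, 1], pr[p, 2]] <- p
    pidx[pr[p, 2], pr[p, 1]] <- p
  }
  N <- n + npair
  Lext <- matrix(0, N, N)
  Lext[seq_len(n), seq_len(n)] <- L
  Lext[n + seq_len(npair), seq_len(n)] <- expansion$Q
  # product rule: d/dt (dx_j dx_k) = sum_m dx_m dx_k L[m,j]
  #                                + sum_m dx_j dx_m L[m,k]
  for (p in seq_len(npair)) {
    j <- pr[p, 1]; k <- pr[p, 2]
    for (m in seq_len(n)) {
      Lext[n + pidx[m, k], n + p] <- Lext[n + pidx[m, k], n + p] + L[m, j]
      Lext[n + pidx[j, m], n + p] <- Lext[n + pidx[j, m], n + p] + L[m, k]
    }
  }
  nm <- c(rownames(L), paste0("(", rownames(L)[pr[, 1]], ",",
                              rownames(L)[pr[, 2]], ")"))
  dimnames(Lext) <- list(nm, nm)
  Lext
}

# Partition an extended matrix into the S/B blocks of the projection
# formulae, retaining the observable metadata.
partition_blocks <- function(Lext, index) {
  S <- index$S; B <- index$B
  lin_s <- which(index$obs$block == "S" & index$obs$kind == "linear")
  list(L_SS = Lext[S, S, drop = FALSE],
       L_SB = Lext[S, B, drop = FALSE],
       L_BB = Lext[B, B, drop = FALSE],
       L_BS = Lext[B, S, drop = FALSE],
       index = index,
       S_names = index$obs$name[S], B_names = index$obs$name[B],
       lin_target_cols = match(lin_s, S))
}

#' Rate matrix of the projected equations
#'
#' The instantaneous subnetwork self-interaction block: the S,S block of the
#' (extended) dynamical matrix.
#'
#' @param blocks block list from a projection (or a
#'   \code{grn_projection}).
#' @return matrix over subnetwork observables, row = source orientation.
#' @export
rate_matrix <- function(blocks) {
  if (inherits(blocks, "grn_projection")) blocks <- blocks$blocks
  blocks$L_SS
}

# Bulk propagators exp(L_BB * dt) over a dt grid; uses a single matrix
# exponential per uniform step (power accumulation), falling back to one
# exponential per point for non-uniform grids.
bulk_propagators <- function(L_BB, dt_grid) {
  stopifnot(all(dt_grid >= 0))
  nb <- nrow(L_BB)
  out <- vector("list", length(dt_grid))
  if (nb == 0) {
    for (i in seq_along(dt_grid)) out[[i]] <- matrix(0, 0, 0)
    return(out)
  }
  ev <- eigen(L_BB, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    warning("bulk block is not stable (spectral abscissa ",
            signif(max(Re(ev)), 3), "); memory will not decay")
  h <- unique(round(diff(dt_grid), 12))
  uniform <- length(dt_grid) > 2 && length(h) == 1 && h[1] > 0 &&
    abs(dt_grid[1]) < 1e-12
  if (uniform) {
    Eh <- as.matrix(Matrix::expm(L_BB * h[1]))
    P <- diag(nb)
    for (i in seq_along(dt_grid)) {
      out[[i]] <- P
      P <- P %*% Eh
    }
  } else {
    for (i in seq_along(dt_grid))
      out[[i]] <- if (dt_grid[i] == 0) diag(nb) else
        as.matrix(Matrix::expm(L_BB * dt_grid[i]))
  }
  out
}

#' Memory functions of the projection
#'
#' Evaluates \eqn{M(\Delta t) = L^{S,B} e^{L^{B,B}\Delta t} L^{B,S}} on a
#' grid of time differences, restricted to columns of the linear subnetwork
#' targets. Rows spanning the linear subnetwork observables are the linear
#' memory functions; rows spanning the quadratic subnetwork observables are
#' the nonlinear memory functions.
#'
#' @param blocks block list or \code{grn_projection}.
#' @param dt_grid non-negative time differences.
#' @return 3-d array \code{[source observable in S, linear subnetwork
#'   target, dt]} with a \code{"dt"} attribute.
#' @export
memory_function <- function(blocks, dt_grid) {
  if (inherits(blocks, "grn_projection")) blocks <- blocks$blocks
  props <- bulk_propagators(blocks$L_BB, dt_grid)
  cols <- blocks$lin_target_cols
  out <- array(0, c(nrow(blocks$L_SB), length(cols), length(dt_grid)),
               dimnames = list(blocks$S_names,
                               blocks$S_names[cols], NULL))
  for (i in seq_along(dt_grid))
    out[, , i] <- (blocks$L_SB %*% props[[i]] %*%
                     blocks$L_BS)[, cols, drop = FALSE]
  attr(out, "dt") <- dt_grid
  out
}

#' Memory amplitudes (memory functions at zero time difference)
#'
#' @param blocks block list or \code{grn_projection}.
#' @return matrix \code{[source observable in S, linear subnetwork target]}.
#' @export
memory_amplitude <- function(blocks) {
  if (inherits(blocks, "grn_projection")) blocks <- blocks$blocks
  m <- memory_function(blocks, 0)
  matrix(m[, , 1], dim(m)[1], dim(m)[2], dimnames = dimnames(m)[1:2])
}

# Channel weight matrix: rows = channels (bulk linear species), columns =
# bulk observables. Entry attribution assigns each bulk observable to the
# bulk species through which the signal enters: a linear bulk deviation to
# itself, a mixed subnetwork-bulk product to its bulk member, a bulk-bulk
# product of one species to that species, and a mixed bulk-bulk product half
# to each member.
channel_weights <- function(index, channels) {
  obs <- index$obs
  B <- index$B
  W <- matrix(0, length(channels), length(B),
              dimnames = list(channels, obs$name[B]))
  bulk_of <- function(row) {
    sp <- c(obs$j[row], obs$k[row])
    sp <- sp[!is.na(sp)]
    nm <- index$species[sp]
    nm[nm %in% index$bulk]
  }
  for (ci in seq_along(B)) {
    row <- B[ci]
    bs <- bulk_of(row)
    if (!length(bs))
      stop("bulk observable without a bulk member: ", obs$name[row])
    for (b in unique(bs))
      if (b %in% channels)
        W[b, ci] <- W[b, ci] + sum(bs == b) / length(bs)
  }
  W
}

#' Decompose memory functions into bulk channels
#'
#' Splits each memory function additively into contributions attributed to
#' individual bulk species. With entry attribution (default) a signal's
#' channel is the bulk observable it first enters from the subnetwork, which
#' makes the channels an exact column partition of \eqn{L^{S,B}}; exit
#' attribution (the bulk observable from which the signal re-enters the
#' subnetwork) is available for comparison. Products of two different bulk
#' species are split half and half between the two channels.
#'
#' @param blocks block list or \code{grn_projection}.
#' @param dt_grid non-negative time differences.
#' @param channels bulk linear species to decompose over (default: all).
#' @param attribution \code{"entry"} or \code{"exit"}.
#' @return list of arrays as in \code{\link{memory_function}}, one per
#'   channel; the arrays sum to the total memory at machine precision.
#' @export
channel_decomposition <- function(blocks, dt_grid, channels = NULL,
                                  attribution = c("entry", "exit")) {
  if (inherits(blocks, "grn_projection")) blocks <- blocks$blocks
  attribution <- match.arg(attribution)
  index <- blocks$index
  if (is.null(channels)) channels <- index$bulk
  if (!all(channels %in% index$bulk))
    stop("unknown channel species: ",
         paste(setdiff(channels, index$bulk), collapse = ", "))
  W <- channel_weights(index, channels)
  props <- bulk_propagators(blocks$L_BB, dt_grid)
  cols <- blocks$lin_target_cols
  out <- lapply(channels, function(ch) {
    w <- W[ch, ]
    arr <- array(0, c(nrow(blocks$L_SB), length(cols), length(dt_grid)),
                 dimnames = list(blocks$S_names, blocks$S_names[cols], NULL))
    for (i in seq_along(dt_grid)) {
      m <- if (attribution == "entry")
        (blocks$L_SB * rep(w, each = nrow(blocks$L_SB))) %*%
          props[[i]] %*% blocks$L_BS
      else
        blocks$L_SB %*% props[[i]] %*% (blocks$L_BS * w)
      arr[, , i] <- m[, cols, drop = FALSE]
    }
    attr(arr, "dt") <- dt_grid
    arr
  })
  names(out) <- channels
  out
}

#' Project a GRN model onto a subnetwork
#'
#' Wires together the Taylor expansion at a steady state, the extended
#' observable matrix, and the subnetwork/bulk block partition, returning the
#' rate matrix and a memory-function evaluator. This is the heuristic route
#' (expansion of the thermodynamic equations, no explicit DNA species),
#' which the network-expansion machinery proves identical to QSS elimination
#' of the fast DNA conformations.
#'
#' @param model a \code{grn_model}.
#' @param y steady state to expand around.
#' @param subnetwork character vector of tracked protein species.
#' @param order \code{"linear"} or \code{"quadratic"}.
#' @return object of class \code{grn_projection} with fields
#'   \code{Omega_ss} (linear rate-matrix block), \code{Omega_qs} (quadratic
#'   source block, quadratic order only), \code{blocks}, \code{index},
#'   \code{expansion}, and the partition.
#' @export
project_subnetwork <- function(model, y, subnetwork,
                               order = c("linear", "quadratic")) {
  order <- match.arg(order)
  expn <- if (order == "quadratic") quadratic_expansion(model, y)
          else linearize(model, y)
  projection_from_expansion(expn, model$proteins, subnetwork, order,
                            model = model)
}

#' Projection of an explicit linear (or linear+quadratic) system
#'
#' Builds a projection directly from a dynamical matrix in row = source
#' orientation (\eqn{\partial_t \delta x^T = \delta x^T L}), optionally with
#' quadratic coefficients. Useful for networks that are already linear and
#' for testing against closed-form solutions.
#'
#' @param L square matrix, row = source, column = target.
#' @param subnetwork character names or integer indices of subnetwork rows.
#' @param Q optional quadratic coefficient matrix (canonical pair rows).
#' @param species optional species names (defaults to rownames or x1..xn).
#' @return \code{grn_projection}.
#' @export
projection_from_matrix <- function(L, subnetwork, Q = NULL, species = NULL) {
  n <- nrow(L)
  if (is.null(species))
    species <- rownames(L) %||% paste0("x", seq_len(n))
  dimnames(L) <- list(species, species)
  if (is.numeric(subnetwork)) subnetwork <- species[subnetwork]
  expn <- structure(list(y = rep(NA_real_, n), L = L, Q = Q,
                         pairs = if (!is.null(Q)) pair_index(n)),
                    class = "grn_taylor")
  order <- if (is.null(Q)) "linear" else "quadratic"
  projection_from_expansion(expn, species, subnetwork, order)
}

projection_from_expansion <- function(expn, species, subnetwork, order,
                                      model = NULL) {
  index <- observable_index(species, subnetwork, order)
  Lext <- build_extended_L(expn, order)
  blocks <- partition_blocks(Lext, index)
  ns <- length(subnetwork)
  lin_rows <- match(which(index$obs$block == "S" &
                            index$obs$kind == "linear"), index$S)
  Omega <- blocks$L_SS
  res <- list(
    model = model, y = expn$y, expansion = expn, order = order,
    subnetwork = subnetwork, bulk = index$bulk,
    index = index, blocks = blocks,
    Omega_ss = Omega[lin_rows, blocks$lin_target_cols, drop = FALSE],
    Omega_qs = if (order == "quadratic")
      Omega[-lin_rows, blocks$lin_target_cols, drop = FALSE],
    # full S-block rate matrix; the quadratic-target columns are internal
    Omega_full = Omega)
  class(res) <- "grn_projection"
  res
}

#' @export
print.grn_projection <- function(x, ...) {
  cat("Zwanzig-Mori projection (", x$order, " order)\n", sep = "")
  cat("  subnetwork:", paste(x$subnetwork, collapse = ", "), "\n")
  cat("  bulk:", if (length(x$bulk)) paste(x$bulk, collapse = ", ")
      else "(empty)", "\n")
  cat("  rate matrix Omega (row = source):\n")
  print(signif(x$Omega_ss, 6))
  invisible(x)
}

#' Closed-form kernel moments of the memory functions
#'
#' Zeroth and first moments of the memory kernel over an infinite horizon,
#' valid for a stable bulk block:
#' \eqn{M_0 = -L^{S,B} (L^{B,B})^{-1} L^{B,S}} and
#' \eqn{M_1 = L^{S,B} (L^{B,B})^{-2} L^{B,S}},
#' restricted to the linear subnetwork target columns.
#'
#' @param blocks block list or \code{grn_projection}.
#' @return list with matrices \code{M0} and \code{M1}.
#' @export
kernel_moments <- function(blocks) {
  if (inherits(blocks, "grn_projection")) blocks <- blocks$blocks
  if (ncol(blocks$L_BB) == 0) {
    z <- matrix(0, nrow(blocks$L_SB), length(blocks$lin_target_cols))
    return(list(M0 = z, M1 = z))
  }
  inv <- solve(blocks$L_BB)
  cols <- blocks$lin_target_cols
  list(M0 = (-blocks$L_SB %*% inv %*% blocks$L_BS)[, cols, drop = FALSE],
       M1 = (blocks$L_SB %*% inv %*% inv %*%
               blocks$L_BS)[, cols, drop = FALSE])
}
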