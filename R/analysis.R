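# Steady-state continuation along a control parameter, memory-amplitude
# profiles per branch and channel, basin-of-attraction scans, and removal of
# regulatory links.

#' Remove a regulatory link from a model
#'
#' Deletes every binding conformation of the target gene in which the
#' regulator is bound (occupancy > 0), removing the regulator's influence on
#' that gene while leaving all other genes untouched.
#'
#' @param model a \code{grn_model}.
#' @param regulator species name (protein or clamped input).
#' @param target_gene gene name.
#' @return the modified \code{grn_model}; if the link is absent the model is
#'   returned unchanged with a warning.
#' @export
link_removal <- function(model, regulator, target_gene) {
  species <- c(model$proteins, names(model$inputs))
  if (!regulator %in% species) stop("unknown regulator: ", regulator)
  gi <- match(target_gene, model$proteins)
  if (is.na(gi)) stop("unknown gene: ", target_gene)
  genes <- lapply(model$genes, function(g) g)
  confs <- genes[[gi]]$conformations
  keep <- vapply(confs, function(cf)
    is.na(match(regulator, names(cf$bound))) || cf$bound[regulator] == 0,
    TRUE)
  if (all(keep)) {
    warning("no binding of '", regulator, "' to gene '", target_gene,
            "': model unchanged")
    return(model)
  }
  genes[[gi]]$conformations <- confs[keep]
  grn_model(model$proteins, genes, model$inputs)
}

#' Steady-state continuation along a control parameter
#'
#' Natural (parameter-stepping) continuation: at each grid point the steady
#' states are located with seeds drawn from the previous point's states plus
#' the user grid, then linked to nearest neighbours between adjacent points
#' to form branches.
#'
#' @param model_family function(parameter) returning a \code{grn_model}.
#' @param grid numeric parameter grid (e.g. signal level or position).
#' @param seeds matrix of seed states (rows) used at every grid point.
#' @param max_jump maximum max-norm distance for linking states of adjacent
#'   grid points into the same branch.
#' @param ... passed to \code{\link{find_steady_states}}.
#' @return object of class \code{grn_bifurcation}: a list with \code{grid},
#'   the per-point state records, and a long-format data.frame \code{table}
#'   (param, branch, species, value, stable).
#' @export
continuation_scan <- function(model_family, grid, seeds, max_jump = 0.5,
                              ...) {
  if (is.list(seeds)) seeds <- do.call(rbind, seeds)
  states <- vector("list", length(grid))
  branches <- vector("list", length(grid))
  next_branch <- 1L
  prev <- NULL
  prev_br <- integer(0)
  for (gi in seq_along(grid)) {
    m <- model_family(grid[gi])
    sd <- seeds
    if (!is.null(prev) && length(prev))
      sd <- rbind(sd, do.call(rbind, lapply(prev, `[[`, "y")))
    recs <- suppressWarnings(find_steady_states(m, sd, ...))
    br <- integer(length(recs))
    if (length(recs)) {
      for (ri in seq_along(recs)) {
        if (!is.null(prev) && length(prev)) {
          dists <- vapply(prev, function(p)
            max(abs(p$y - recs[[ri]]$y)), 0)
          cand <- which.min(dists)
          if (dists[cand] <= max_jump) {
            br[ri] <- prev_br[cand]
            next
          }
        }
        br[ri] <- next_branch
        next_branch <- next_branch + 1L
      }
    }
    states[[gi]] <- recs
    branches[[gi]] <- br
    prev <- recs
    prev_br <- br
  }
  tab <- do.call(rbind, lapply(seq_along(grid), function(gi) {
    recs <- states[[gi]]
    if (!length(recs)) return(NULL)
    do.call(rbind, lapply(seq_along(recs), function(ri)
      data.frame(param = grid[gi], branch = branches[[gi]][ri],
                 species = names(recs[[ri]]$y),
                 value = as.numeric(recs[[ri]]$y),
                 stable = recs[[ri]]$stable,
                 row.names = NULL, stringsAsFactors = FALSE)))
  }))
  structure(list(grid = grid, states = states, branches = branches,
                 table = tab),
            class = "grn_bifurcation")
}

#' @export
print.grn_bifurcation <- function(x, ...) {
  ns <- vapply(x$states, length, 0)
  cat("Bifurcation scan over", length(x$grid), "parameter values;",
      "steady states per point:", paste(range(ns), collapse = "-"), "\n")
  invisible(x)
}

#' Memory-amplitude profile along a parameter scan
#'
#' For every steady state on every branch of a continuation scan, projects
#' the model onto the given subnetwork and records the memory amplitudes
#' (memory functions at zero time difference), total and per bulk channel.
#'
#' @param model_family function(parameter) returning a \code{grn_model}.
#' @param subnetwork character vector of subnetwork species.
#' @param grid parameter grid.
#' @param seeds seed states for the steady-state search.
#' @param order projection order.
#' @param ... passed to \code{\link{continuation_scan}}.
#' @return long-format data.frame: param, branch, stable, source, target,
#'   channel ("total" or a bulk species), value.
#' @export
amplitude_profile <- function(model_family, subnetwork, grid, seeds,
                              order = "linear", ...) {
  scan <- continuation_scan(model_family, grid, seeds, ...)
  rows <- list()
  for (gi in seq_along(grid)) {
    m <- model_family(grid[gi])
    recs <- scan$states[[gi]]
    for (ri in seq_along(recs)) {
      proj <- project_subnetwork(m, recs[[ri]]$y, subnetwork, order = order)
      amp <- memory_function(proj, 0)
      chans <- channel_decomposition(proj, 0)
      src <- dimnames(amp)[[1]]
      tgt <- dimnames(amp)[[2]]
      for (s in seq_along(src)) for (t in seq_along(tgt)) {
        rows[[length(rows) + 1]] <- data.frame(
          param = grid[gi], branch = scan$branches[[gi]][ri],
          stable = recs[[ri]]$stable, source = src[s], target = tgt[t],
          channel = c("total", names(chans)),
          value = c(amp[s, t, 1],
                    vapply(chans, function(a) a[s, t, 1], 0)),
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Basin-of-attraction scan
#'
#' Integrates the full dynamics from each initial state in a grid and labels
#' the endpoint by the nearest steady state (after a Newton polish), or
#' "unresolved" when no steady state is within tolerance.
#'
#' @param model a \code{grn_model}.
#' @param ic_grid matrix of initial states (rows) over the proteins.
#' @param t_final integration horizon; default 50 slowest decay times.
#' @param states optional list of steady-state records to classify against
#'   (default: \code{find_steady_states} seeded with the grid).
#' @param class_tol classification tolerance in max-norm (default 10x the
#'   steady-state dedup tolerance).
#' @return data.frame with the initial-state coordinates and a \code{label}
#'   column (index into \code{states}, or NA for unresolved).
#' @export
basin_scan <- function(model, ic_grid, t_final = NULL, states = NULL,
                       class_tol = 1e-5) {
  ic_grid <- matrix(as.numeric(ic_grid), ncol = length(model$proteins))
  if (is.null(t_final))
    t_final <- 50 / min(vapply(model$genes, `[[`, 0, "beta"))
  if (is.null(states))
    states <- find_steady_states(model, ic_grid)
  ymat <- do.call(rbind, lapply(states, `[[`, "y"))
  labels <- integer(nrow(ic_grid))
  for (r in seq_len(nrow(ic_grid))) {
    tr <- tryCatch(simulate_full(model, ic_grid[r, ], c(0, t_final)),
                   error = function(e) NULL)
    lab <- NA_integer_
    if (!is.null(tr)) {
      xe <- as.numeric(tr[nrow(tr), -1])
      xp <- newton_root(model, xe)
      if (!is.null(xp)) xe <- xp
      d <- apply(abs(ymat - matrix(xe, nrow(ymat), ncol(ymat),
                                   byrow = TRUE)), 1, max)
      if (min(d) < class_tol) lab <- which.min(d)
    }
    labels[r] <- lab
  }
  out <- as.data.frame(ic_grid)
  names(out) <- model$proteins
  out$label <- labels
  attr(out, "states") <- states
  out
}
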