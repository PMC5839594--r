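# Model-spec serialisation (JSON), shipped fixtures, seeded random model
# generation, and CSV table output with metadata headers.

#' Read a GRN model from a JSON specification
#'
#' The schema has top-level keys \code{proteins} (array of names),
#' \code{inputs} (object name -> clamped concentration, optional) and
#' \code{genes} (array of objects with \code{name}, \code{beta},
#' \code{conformations}; each conformation has \code{bound} (object species
#' -> copy count), \code{weight} and \code{alpha}). Concentrations are
#' dimensionless; time is in units of inverse decay rates unless stated by
#' the model author.
#'
#' @param path file path.
#' @return a \code{grn_model}.
#' @export
read_grn_model <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  known <- c("proteins", "inputs", "genes")
  extra <- setdiff(names(spec), known)
  if (length(extra))
    stop("unknown model-spec key(s): ", paste(extra, collapse = ", "))
  if (is.null(spec$proteins) || is.null(spec$genes))
    stop("model spec needs 'proteins' and 'genes'")
  inputs <- if (is.null(spec$inputs)) numeric(0) else
    unlist(spec$inputs)
  genes <- lapply(spec$genes, function(g) {
    extra <- setdiff(names(g), c("name", "beta", "conformations"))
    if (length(extra))
      stop("unknown gene key(s): ", paste(extra, collapse = ", "))
    confs <- lapply(g$conformations, function(cf) {
      extra <- setdiff(names(cf), c("bound", "weight", "alpha"))
      if (length(extra))
        stop("unknown conformation key(s): ", paste(extra, collapse = ", "))
      b <- if (is.null(cf$bound) || !length(cf$bound)) integer(0) else
        unlist(cf$bound)
      list(bound = b, weight = cf$weight, alpha = cf$alpha)
    })
    list(name = g$name, beta = g$beta, conformations = confs)
  })
  grn_model(unlist(spec$proteins), genes, inputs)
}

#' Write a GRN model to a JSON specification
#'
#' Weights and rates are serialised at full precision, so a write/read
#' round trip reproduces the model exactly.
#'
#' @param model a \code{grn_model}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_grn_model <- function(model, path) {
  spec <- list(
    proteins = model$proteins,
    inputs = as.list(model$inputs),
    genes = lapply(model$genes, function(g) list(
      name = g$name, beta = g$beta,
      conformations = lapply(g$conformations, function(cf) list(
        bound = as.list(cf$bound), weight = cf$weight, alpha = cf$alpha)))))
  if (!length(model$inputs)) spec$inputs <- NULL
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Built-in example models
#'
#' \describe{
#'   \item{cross_repression}{Two genes, each repressing the other
#'     through a single binding site. Production of gene 1 is
#'     \eqn{\alpha_1 / (w_1 + w_{p2} x_2)} (and conversely), encoded as an
#'     unbound conformation (weight \eqn{w_1}, rate \eqn{\alpha_1/w_1}) and
#'     a repressor-bound conformation (weight \eqn{w_{p2}}, rate 0) so the
#'     ensemble form reproduces that rational production law exactly.
#'     Parameters: \eqn{\alpha_1 = \alpha_2 = 1}, \eqn{w_{p1} = 1},
#'     \eqn{w_{p2} = 2}, \eqn{w_1 = w_2 = 2},
#'     \eqn{\beta_1 = \beta_2 = 1/2}. Monostable.}
#'   \item{cross_repression_bistable}{The same motif with two binding sites
#'     per gene (weights 1, \eqn{w_p x}, \eqn{w_p^2 x^2}; production only
#'     from the unbound state), parameterised to be bistable:
#'     \eqn{w_p = 3}, \eqn{\alpha = 1}, \eqn{\beta = 1/4}.}
#'   \item{neural_tube_like}{A synthetic four-gene network copying the
#'     topology of the ventral neural tube circuit (mutual repressions among
#'     N, O, P, I and an activating clamped input on N and O), with
#'     round-number parameters chosen so a signal scan shows at least three
#'     dominant-factor regions. It is not the published neural-tube
#'     parameterisation. The clamped input \code{sig} is the scan parameter;
#'     use \code{\link{neural_tube_family}}.}
#' }
#'
#' @param name fixture name.
#' @return a \code{grn_model}.
#' @export
make_fixture <- function(name = c("cross_repression",
                                  "cross_repression_bistable",
                                  "neural_tube_like")) {
  name <- match.arg(name)
  switch(name,
    cross_repression = {
      a1 <- 1; a2 <- 1; wp1 <- 1; wp2 <- 2; w1 <- 2; w2 <- 2
      grn_model(
        proteins = c("g1", "g2"),
        genes = list(
          list(name = "g1", beta = 0.5, conformations = list(
            list(bound = NULL, weight = w1, alpha = a1 / w1),
            list(bound = c(g2 = 1), weight = wp2, alpha = 0))),
          list(name = "g2", beta = 0.5, conformations = list(
            list(bound = NULL, weight = w2, alpha = a2 / w2),
            list(bound = c(g1 = 1), weight = wp1, alpha = 0)))))
    },
    cross_repression_bistable = {
      wp <- 3; alpha <- 1; beta <- 0.25
      two_site <- function(self, other) {
        list(name = self, beta = beta, conformations = list(
          list(bound = NULL, weight = 1, alpha = alpha),
          list(bound = stats::setNames(1L, other), weight = wp, alpha = 0),
          list(bound = stats::setNames(2L, other), weight = wp^2,
               alpha = 0)))
      }
      grn_model(c("g1", "g2"),
                list(two_site("g1", "g2"), two_site("g2", "g1")))
    },
    neural_tube_like = neural_tube_family(1)
  )
}

#' Synthetic neural-tube-like model family
#'
#' Four mutually repressing factors N, O, P, I with an activating clamped
#' input \code{sig} on N and O; \code{sig} plays the role of the ventral
#' signal level (position 0 = maximal signal corresponds to
#' \code{sig = 1}). Repressive links: P and I and O repress N; N and I
#' repress O; N and O repress P (the O -> P link is the one whose removal
#' the robustness analysis studies); N and O repress I. All decay rates are
#' 1 and parameters are round numbers; the family is a synthetic stand-in
#' with the published circuit's topology, not its parameter values.
#'
#' @param sig clamped signal level in [0, 1].
#' @return a \code{grn_model} with proteins N, O, P, I.
#' @export
neural_tube_family <- function(sig) {
  stopifnot(is.finite(sig), sig >= 0)
  grn_model(
    proteins = c("N", "O", "P", "I"),
    inputs = c(sig = sig),
    genes = list(
      # N needs two bound signal-effector copies (sharp ventral response);
      # P is its decisive repressor (two sites), O and I are weaker
      list(name = "N", beta = 1, conformations = list(
        list(bound = NULL, weight = 1, alpha = 0),
        list(bound = c(sig = 1), weight = 2, alpha = 0),
        list(bound = c(sig = 2), weight = 4, alpha = 4),
        list(bound = c(P = 1), weight = 8, alpha = 0),
        list(bound = c(P = 2), weight = 64, alpha = 0),
        list(bound = c(I = 1), weight = 3, alpha = 0),
        list(bound = c(O = 1), weight = 2, alpha = 0),
        list(bound = c(O = 2), weight = 4, alpha = 0))),
      # O responds to a single effector copy (turns on at lower signal)
      # and is strongly repressed by N
      list(name = "O", beta = 1, conformations = list(
        list(bound = NULL, weight = 1, alpha = 0),
        list(bound = c(sig = 1), weight = 10, alpha = 2),
        list(bound = c(N = 1), weight = 5, alpha = 0),
        list(bound = c(N = 2), weight = 25, alpha = 0),
        list(bound = c(I = 1), weight = 4, alpha = 0))),
      # P is constitutive, repressed weakly by N and strongly by O
      # (the O -> P link is the removable one)
      list(name = "P", beta = 1, conformations = list(
        list(bound = NULL, weight = 1, alpha = 1.2),
        list(bound = c(N = 1), weight = 1.5, alpha = 0),
        list(bound = c(N = 2), weight = 2.25, alpha = 0),
        list(bound = c(O = 1), weight = 3, alpha = 0),
        list(bound = c(O = 2), weight = 9, alpha = 0))),
      # I is constitutive, repressed by both N and O
      list(name = "I", beta = 1, conformations = list(
        list(bound = NULL, weight = 1, alpha = 1.2),
        list(bound = c(N = 1), weight = 3, alpha = 0),
        list(bound = c(N = 2), weight = 9, alpha = 0),
        list(bound = c(O = 1), weight = 3, alpha = 0),
        list(bound = c(O = 2), weight = 9, alpha = 0)))))
}

#' Seeded random GRN model generator
#'
#' Draws a model with \code{n_genes} proteins. Every gene has an unbound
#' conformation and between one and \code{max_sites} single-copy binding
#' conformations by regulators chosen among the other proteins; bound
#' conformations are repressing (zero production) with probability 1/2,
#' otherwise produce at their own sampled rate. Weights are log-uniform in
#' [0.1, 10], production rates uniform in [0.5, 2], decay rates uniform in
#' [0.2, 2]. Regeneration is attempted (up to 10 times) until at least one
#' steady state is found from a small seed grid.
#'
#' @param n_genes number of genes/proteins.
#' @param max_sites maximum number of regulators binding each gene.
#' @param seed integer seed; the draw is reproducible.
#' @return a \code{grn_model}.
#' @export
random_grn_model <- function(n_genes, max_sites = 1, seed) {
  stopifnot(n_genes >= 2, max_sites >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  proteins <- paste0("g", seq_len(n_genes))
  for (attempt in seq_len(10)) {
    genes <- lapply(seq_len(n_genes), function(i) {
      others <- setdiff(seq_len(n_genes), i)
      nreg <- sample(seq_len(min(max_sites, length(others))), 1)
      regs <- sample(others, nreg)
      confs <- list(list(bound = NULL,
                         weight = exp(stats::runif(1, log(0.1), log(10))),
                         alpha = stats::runif(1, 0.5, 2)))
      for (r in regs) {
        repress <- stats::runif(1) < 0.5
        confs[[length(confs) + 1]] <- list(
          bound = stats::setNames(1L, proteins[r]),
          weight = exp(stats::runif(1, log(0.1), log(10))),
          alpha = if (repress) 0 else stats::runif(1, 0.5, 2))
      }
      list(name = proteins[i], beta = stats::runif(1, 0.2, 2),
           conformations = confs)
    })
    m <- grn_model(proteins, genes)
    ss <- suppressWarnings(
      find_steady_states(m, matrix(1, 1, n_genes), ode_seeds = TRUE))
    if (length(ss)) return(m)
  }
  stop("failed to generate a model with a locatable steady state in 10 attempts")
}

#' Write a data table as CSV with metadata header lines
#'
#' Metadata (seed, configuration, etc.) is written as '#'-prefixed lines
#' before the header, a convention the reader tolerates.
#'
#' @param x data.frame.
#' @param path file path.
#' @param meta named character/numeric vector written as '# name: value'.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by \code{\link{write_table_csv}}
#' @param path file path.
#' @return data.frame (metadata lines are skipped).
#' @export
read_table_csv <- function(path)
  utils::read.csv(path, comment.char = "#")

#' Memory functions as a long-format table
#'
#' @param m array from \code{\link{memory_function}} (or one channel of
#'   \code{\link{channel_decomposition}}).
#' @return data.frame with columns dt, source, target, value.
#' @export
memory_table <- function(m) {
  dt <- attr(m, "dt")
  dn <- dimnames(m)
  out <- expand.grid(source = dn[[1]], target = dn[[2]], dt = dt,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- as.numeric(m)
  out[c("dt", "source", "target", "value")]
}
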