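## Prior specifications -------------------------------------------------
##
## A prior_spec holds, for each of the three model groups (iso, recent,
## ancient), an ordered list of parameter descriptors. A descriptor is
## either
##   list(dist = "unif", min =, max =, min_param =, max_param =)
## where min_param / max_param (optional) name an earlier parameter whose
## sampled value tightens the bound (conditional truncated uniform), or
##   list(dist = "exp", mean =)
## Group-level constraints are limited to sum rules
##   list(type = "sum_le", a =, b =, c =)   # a + b <= c, enforced on b
## which are honoured by redrawing `b` (and, if the rule is unsatisfiable
## for the current draw, redrawing the whole vector).

MODEL_IDS <- c("A", "B", "C", "D", "E", "F", "ISO")

model_group <- function(model_id) {
  switch(model_id,
    A = , B = , D = , E = "recent",
    C = , F = "ancient",
    ISO = "iso",
    stop("unknown model id: ", model_id))
}

#' Built-in prior presets
#'
#' Two presets are provided. `"simulation"` is the continuous-admixture
#' configuration used for the simulation-study design: theta ~ U(0.007,
#' 0.35) (i.e. 4*Ne*mu*L for Ne in 2000--100000, mu = 1.75e-9, L = 500
#' bp), Tgf ~ U(0.1, 0.5), T1 ~ U(0.4, 1) truncated to T1 > Tgf,
#' T2 ~ U(1, 4), Tdur ~ U(0.01, 0.1) with Tgf + Tdur <= T1, and
#' 4Nm ~ E(0.1) (see `nm_exponential`). `"empirical"` is the pulse-admixture
#' configuration: theta ~ U(0.01, 1.4), Tgf ~ U(0.1, 2),
#' T1 ~ U(0.1, 4 | T1 > Tgf), T2 ~ U(0.1, 4 | T2 > T1) and F ~ U(0, 1).
#' In both presets, the ancient-admixture models (C, F) instead use
#' T1 ~ U(0.1, 4), T2 ~ U(T1, 4) and Tgf ~ U(T1, T2), so that the
#' admixture episode falls between the two splits. Times are in units of
#' 4*Ne generations; theta is per whole locus.
#'
#' @param name `"simulation"` (continuous-window admixture) or
#'   `"empirical"` (pulse admixture).
#' @param nm_exponential how the `E(0.1)` prior on the gene-flow
#'   magnitude is parameterized: `"rate"` (the default; exponential with
#'   rate 0.1, i.e. mean 4Nm = 10) or `"mean"` (mean 0.1). The rate
#'   reading is the package default because only appreciable gene flow
#'   makes the admixture models distinguishable from isolation — under
#'   mean 0.1 virtually every draw is effectively gene-flow-free and the
#'   recent-admixture models collapse onto ISO (see the methods
#'   vignette).
#' @return an object of class `prior_spec`.
#' @seealso [sample_prior()], [read_prior_config()]
#' @export
#' @examples
#' pr <- prior_preset("simulation")
#' sample_prior("A", pr, n = 3)
prior_preset <- function(name = c("simulation", "empirical"),
                         nm_exponential = c("rate", "mean")) {
  name <- match.arg(name)
  nm_exponential <- match.arg(nm_exponential)
  nm_mean <- if (nm_exponential == "rate") 1 / 0.1 else 0.1
  un <- function(min, max, min_param = NULL, max_param = NULL) {
    d <- list(dist = "unif", min = min, max = max)
    if (!is.null(min_param)) d$min_param <- min_param
    if (!is.null(max_param)) d$max_param <- max_param
    d
  }
  if (name == "simulation") {
    theta <- un(0.007, 0.35)
    groups <- list(
      iso = list(theta = theta, T1 = un(0.4, 1), T2 = un(1, 4)),
      recent = list(
        theta = theta,
        Tgf  = un(0.1, 0.5),
        T1   = un(0.4, 1, min_param = "Tgf"),
        T2   = un(1, 4),
        Tdur = un(0.01, 0.1),
        Nm4  = list(dist = "exp", mean = nm_mean)),
      ancient = list(
        theta = theta,
        T1   = un(0.1, 4),
        T2   = un(0.1, 4, min_param = "T1"),
        Tgf  = un(0.1, 4, min_param = "T1", max_param = "T2"),
        Tdur = un(0.01, 0.1),
        Nm4  = list(dist = "exp", mean = nm_mean)))
    constraints <- list(
      recent  = list(list(type = "sum_le", a = "Tgf", b = "Tdur", c = "T1")),
      ancient = list(list(type = "sum_le", a = "Tgf", b = "Tdur", c = "T2")))
    mode <- "continuous_window"
  } else {
    theta <- un(0.01, 1.4)
    groups <- list(
      iso = list(theta = theta, T1 = un(0.1, 4), T2 = un(0.1, 4, min_param = "T1")),
      recent = list(
        theta = theta,
        Tgf = un(0.1, 2),
        T1  = un(0.1, 4, min_param = "Tgf"),
        T2  = un(0.1, 4, min_param = "T1"),
        F   = un(0, 1)),
      ancient = list(
        theta = theta,
        T1  = un(0.1, 4),
        T2  = un(0.1, 4, min_param = "T1"),
        Tgf = un(0.1, 4, min_param = "T1", max_param = "T2"),
        F   = un(0, 1)))
    constraints <- list(recent = list(), ancient = list())
    mode <- "pulse"
  }
  structure(list(name = name, admixture_mode = mode, groups = groups,
                 constraints = constraints),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification '", x$name, "' (", x$admixture_mode, ")\n", sep = "")
  for (g in names(x$groups)) {
    cat("  group ", g, ": ", sep = "")
    cat(vapply(names(x$groups[[g]]), function(p) {
      d <- x$groups[[g]][[p]]
      if (d$dist == "unif") {
        lo <- if (!is.null(d$min_param)) paste0("max(", d$min, ",", d$min_param, ")") else d$min
        hi <- if (!is.null(d$max_param)) paste0("min(", d$max, ",", d$max_param, ")") else d$max
        sprintf("%s~U(%s,%s)", p, lo, hi)
      } else sprintf("%s~Exp(mean %g)", p, d$mean)
    }, ""), sep = " ")
    cat("\n")
  }
  invisible(x)
}

draw_one_param <- function(desc, vals, n) {
  if (desc$dist == "unif") {
    lo <- rep(desc$min, n)
    hi <- rep(desc$max, n)
    if (!is.null(desc$min_param)) lo <- pmax(lo, vals[[desc$min_param]])
    if (!is.null(desc$max_param)) hi <- pmin(hi, vals[[desc$max_param]])
    if (any(hi < lo)) stop("empty truncated-uniform support for a prior draw")
    runif(n, lo, hi)
  } else if (desc$dist == "exp") {
    rexp(n, rate = 1 / desc$mean)
  } else stop("unknown prior distribution: ", desc$dist)
}

#' Draw model parameters from a prior specification
#'
#' Samples parameter vectors for one demographic model, honouring the
#' conditional truncation rules of the prior specification (e.g. T1 > Tgf for
#' recent-admixture models, T1 < Tgf < T2 for ancient ones, and
#' Tgf + Tdur inside the relevant inter-split window for
#' continuous-window admixture). Draws are reproducible under
#' [set.seed()].
#'
#' @param model a model id (`"A"`,...,`"F"`, `"ISO"`) or a [model_spec()].
#' @param priors a `prior_spec`, e.g. from [prior_preset()].
#' @param n number of draws.
#' @return a data.frame with one row per draw and one column per model
#'   parameter (`theta`, `T1`, `T2` and, depending on the model and
#'   admixture mode, `Tgf`, `Tdur`, `Nm4` or `F`).
#' @export
sample_prior <- function(model, priors, n = 1) {
  model_id <- if (inherits(model, "model_spec")) model$model_id else match.arg(model, MODEL_IDS)
  if (inherits(model, "model_spec") && model$admixture_mode != priors$admixture_mode &&
      model_id != "ISO")
    stop("priors were built for admixture mode '", priors$admixture_mode,
         "' but the model uses '", model$admixture_mode, "'")
  stopifnot(inherits(priors, "prior_spec"), n >= 0)
  grp <- model_group(model_id)
  descs <- priors$groups[[grp]]
  cons <- priors$constraints[[grp]] %||% list()
  if (n == 0)
    return(as.data.frame(setNames(rep(list(numeric(0)), length(descs)), names(descs))))

  draw_block <- function(n) {
    vals <- list()
    for (p in names(descs)) vals[[p]] <- draw_one_param(descs[[p]], vals, n)
    for (cn in cons) {
      if (cn$type != "sum_le") stop("unknown constraint type: ", cn$type)
      bad <- vals[[cn$a]] + vals[[cn$b]] > vals[[cn$c]]
      tries <- 0L
      while (any(bad) && tries < 50L) {
        redraw <- draw_one_param(descs[[cn$b]], vals, sum(bad))
        vals[[cn$b]][bad] <- redraw
        bad <- vals[[cn$a]] + vals[[cn$b]] > vals[[cn$c]]
        tries <- tries + 1L
      }
      if (any(bad)) {
        # window cannot accommodate the minimum duration: redraw whole rows
        sub <- draw_block(sum(bad))
        for (p in names(descs)) vals[[p]][bad] <- sub[[p]]
      }
    }
    as.data.frame(vals)
  }
  out <- draw_block(n)
  names(out) <- names(descs)
  out
}

#' Envelope support and transform for each model parameter
#'
#' Returns, for each parameter of `model` under `priors`, the widest
#' interval any draw can fall in (ignoring conditional truncation, which
#' only narrows it) plus the unbounding transform used by the
#' regression-adjustment machinery: `logit` for bounded uniforms, `log`
#' for positive exponentials.
#'
#' @inheritParams sample_prior
#' @return data.frame with columns `param`, `lo`, `hi`, `trans`.
#' @export
param_support <- function(model, priors) {
  model_id <- if (inherits(model, "model_spec")) model$model_id else match.arg(model, MODEL_IDS)
  descs <- priors$groups[[model_group(model_id)]]
  out <- data.frame(param = names(descs), lo = NA_real_, hi = NA_real_,
                    trans = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(descs)) {
    d <- descs[[i]]
    if (d$dist == "unif") {
      out$lo[i] <- d$min; out$hi[i] <- d$max; out$trans[i] <- "logit"
    } else {
      out$lo[i] <- 0; out$hi[i] <- Inf; out$trans[i] <- "log"
    }
  }
  out
}

## Monte-Carlo prior moments (conditional priors have no simple closed
## form); seeded for reproducibility.
prior_moments <- function(model, priors, n = 100000L, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- sample_prior(model, priors, n = n)
  list(mean = vapply(draws, mean, 0), var = vapply(draws, var, 0),
       hpd_width = vapply(draws, function(x) {
         iv <- hpd_interval(x, mass = 0.95); iv[2] - iv[1]
       }, 0))
}

#' Validate a parameter vector against a model's invariants
#'
#' Checks positivity, ordering of split times and placement of the
#' admixture episode for the given model.
#'
#' @param model model id or [model_spec()].
#' @param params a named list / one-row data.frame of parameter values.
#' @param admixture_mode `"continuous_window"` or `"pulse"`.
#' @return invisibly `TRUE`; errors describe the first violated rule.
#' @export
validate_params <- function(model, params,
                            admixture_mode = c("continuous_window", "pulse")) {
  model_id <- if (inherits(model, "model_spec")) model$model_id else match.arg(model, MODEL_IDS)
  if (inherits(model, "model_spec")) admixture_mode <- model$admixture_mode
  admixture_mode <- match.arg(admixture_mode)
  p <- as.list(params)
  chk <- function(ok, msg) if (!isTRUE(all(ok))) stop("invalid parameters for model ",
                                                      model_id, ": ", msg)
  chk(p$theta > 0, "theta must be positive")
  chk(p$T1 > 0 && p$T2 > 0, "split times must be positive")
  chk(p$T1 < p$T2, "T1 must precede T2")
  grp <- model_group(model_id)
  if (grp == "iso") return(invisible(TRUE))
  chk(p$Tgf > 0, "Tgf must be positive")
  dur <- if (admixture_mode == "continuous_window") {
    chk(!is.null(p$Tdur) && p$Tdur > 0, "Tdur must be positive")
    chk(!is.null(p$Nm4) && p$Nm4 >= 0, "Nm4 must be nonnegative")
    p$Tdur
  } else {
    chk(!is.null(p$F) && p$F >= 0 && p$F <= 1, "F must lie in [0, 1]")
    0
  }
  if (grp == "recent") {
    chk(p$Tgf < p$T1, "recent admixture requires Tgf < T1")
    chk(p$Tgf + dur <= p$T1, "admixture window must end before T1")
  } else {
    chk(p$T1 <= p$Tgf, "ancient admixture requires Tgf >= T1")
    chk(p$Tgf + dur <= p$T2, "admixture window must end before T2")
  }
  invisible(TRUE)
}

## ---- YAML serialization ----------------------------------------------

#' Read / write a prior specification as YAML
#'
#' The schema mirrors the internal structure: top-level `name`,
#' `admixture_mode`, `groups` (named `iso` / `recent` / `ancient`, each a
#' named list of descriptors with `dist: unif|exp`, bounds, and optional
#' `min_param` / `max_param` conditioning on earlier parameters) and
#' `constraints` (per group, a list of `{type: sum_le, a:, b:, c:}`
#' rules). Serialising and re-reading a specification reproduces
#' identical samples under identical seeds.
#'
#' @param path file path.
#' @return `read_prior_config()` returns a `prior_spec`.
#' @export
read_prior_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$groups), !is.null(y$admixture_mode))
  structure(list(name = y$name %||% "custom",
                 admixture_mode = y$admixture_mode,
                 groups = y$groups,
                 constraints = y$constraints %||%
                   setNames(vector("list", length(y$groups)), names(y$groups))),
            class = "prior_spec")
}

#' @rdname read_prior_config
#' @param priors a `prior_spec`.
#' @export
write_prior_config <- function(priors, path) {
  stopifnot(inherits(priors, "prior_spec"))
  yaml::write_yaml(unclass(priors), path)
  invisible(path)
}
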