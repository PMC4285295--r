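## Candidate demographic histories ---------------------------------------
##
## Fixed topology: populations 2 and 3 are sisters merging (backward in
## time) at T1 into an ancestor carried under label 2, which merges with
## population 1 at T2. Seven candidate models differ in the presence,
## timing and direction of admixture:
##
##   ISO  no gene flow;
##   A/B  "recent" admixture (window after the sister split, forward in
##        time): migrants flow INTO the early-diverging population 1,
##        from population 2 (A) or 3 (B);
##   D/E  recent admixture FROM population 1 into population 2 (D) or
##        3 (E);
##   C/F  "ancient" admixture between T1 and T2, between population 1 and
##        the (2,3) ancestor: C sends ancestor -> population 1, F sends
##        population 1 -> ancestor.
##
## These direction conventions are symmetric within each pair and are held
## fixed throughout the package.

## forward-time direction conventions, expressed as the BACKWARD move:
## lineages of `pop` (the forward-time recipient) jump to `dest` (the
## forward-time source).
.DIRECTIONS <- list(
  A = c(pop = 1, dest = 2),
  B = c(pop = 1, dest = 3),
  C = c(pop = 1, dest = 2),  # ancestor(2,3) carries label 2 beyond T1
  D = c(pop = 2, dest = 1),
  E = c(pop = 3, dest = 1),
  F = c(pop = 2, dest = 1))

#' Specify one of the seven candidate demographic models
#'
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"F"`,
#'   `"ISO"`.
#' @param admixture_mode `"continuous_window"` (gene flow at rate 4Nm
#'   over `[Tgf, Tgf + Tdur]`) or `"pulse"` (instantaneous admixture of
#'   proportion `F` at `Tgf`). Ignored for `"ISO"`.
#' @param population_labels optional character triple naming populations
#'   1 (first-diverging), 2 and 3 (sisters splitting at T1).
#' @return an object of class `model_spec`.
#' @export
#' @examples
#' model_spec("D")
#' model_spec("A", "pulse")
model_spec <- function(model_id = MODEL_IDS,
                       admixture_mode = c("continuous_window", "pulse"),
                       population_labels = c("pop1", "pop2", "pop3")) {
  model_id <- match.arg(model_id)
  admixture_mode <- match.arg(admixture_mode)
  stopifnot(length(population_labels) == 3)
  structure(list(model_id = model_id,
                 admixture_mode = admixture_mode,
                 timing = model_group(model_id),
                 population_labels = population_labels),
            class = "model_spec")
}

as_model_spec <- function(x, admixture_mode = "continuous_window") {
  if (inherits(x, "model_spec")) x else model_spec(x, admixture_mode)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model", x$model_id,
      if (x$model_id == "ISO") "(isolation, no gene flow)"
      else sprintf("(%s admixture, %s)", x$timing, x$admixture_mode), "\n")
  if (x$model_id != "ISO") {
    d <- .DIRECTIONS[[x$model_id]]
    cat(sprintf("  forward-time migrants: %s -> %s\n",
                x$population_labels[d[["dest"]]], x$population_labels[d[["pop"]]]))
  }
  invisible(x)
}

#' Translate a model and parameters into a backward-in-time demography
#'
#' Builds the event plan consumed by the coalescent engine: population
#' merges at `T1` (3 into 2) and `T2` (2 into 1); for continuous-window
#' admixture, one migration epoch over `[Tgf, Tgf + Tdur]` at rate
#' `Nm4` (= 4Nm, per-lineage backward rate per 4Ne generations); for
#' pulse admixture, one mass-migration event at `Tgf` moving each lineage
#' of the forward-time recipient with probability `F`. All populations
#' have equal size 1. Times are in units of 4Ne generations.
#'
#' @param model model id or [model_spec()].
#' @param params named list / one-row data.frame, see [sample_prior()].
#' @return an object of class `demography_plan` with elements `merges`
#'   (`time, from, to`), `epochs` (`start, end, pop, dest, rate`) and
#'   `pulses` (`time, pop, dest, prob`), all in backward-time semantics.
#' @export
#' @examples
#' p <- sample_prior("D", prior_preset("simulation"))
#' build_demography("D", p)
build_demography <- function(model, params) {
  spec <- as_model_spec(model)
  params <- as.list(params)
  validate_params(spec, params)
  merges <- rbind(c(time = params$T1, from = 3, to = 2),
                  c(time = params$T2, from = 2, to = 1))
  epochs <- matrix(numeric(0), 0, 5,
                   dimnames = list(NULL, c("start", "end", "pop", "dest", "rate")))
  pulses <- matrix(numeric(0), 0, 4,
                   dimnames = list(NULL, c("time", "pop", "dest", "prob")))
  if (spec$model_id != "ISO") {
    d <- .DIRECTIONS[[spec$model_id]]
    if (spec$admixture_mode == "continuous_window") {
      epochs <- matrix(c(params$Tgf, params$Tgf + params$Tdur,
                         d[["pop"]], d[["dest"]], params$Nm4), 1, 5,
                       dimnames = list(NULL, c("start", "end", "pop", "dest", "rate")))
    } else {
      pulses <- matrix(c(params$Tgf, d[["pop"]], d[["dest"]], params$F), 1, 4,
                       dimnames = list(NULL, c("time", "pop", "dest", "prob")))
    }
  }
  structure(list(model_id = spec$model_id,
                 admixture_mode = spec$admixture_mode,
                 merges = merges, epochs = epochs, pulses = pulses,
                 params = params),
            class = "demography_plan")
}

#' @export
print.demography_plan <- function(x, ...) {
  cat("Demography plan (model ", x$model_id, ", backward time, 4Ne units)\n",
      sep = "")
  cat(sprintf("  merge: pop3 -> pop2 at t = %.4g\n", x$merges[1, "time"]))
  cat(sprintf("  merge: pop2 -> pop1 at t = %.4g\n", x$merges[2, "time"]))
  if (nrow(x$epochs))
    cat(sprintf("  migration epoch: pop%d -> pop%d over [%.4g, %.4g], rate 4Nm = %.4g\n",
                x$epochs[1, "pop"], x$epochs[1, "dest"],
                x$epochs[1, "start"], x$epochs[1, "end"], x$epochs[1, "rate"]))
  if (nrow(x$pulses))
    cat(sprintf("  pulse: pop%d -> pop%d at t = %.4g, proportion %.4g\n",
                x$pulses[1, "pop"], x$pulses[1, "dest"],
                x$pulses[1, "time"], x$pulses[1, "prob"]))
  invisible(x)
}
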