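#' Demographic scenarios: divergence/admixture event lists with priors
#'
#' A scenario describes, backward in time, the demographic history of a set
#' of sampled populations (plus optional unsampled "ghost" branches): per-deme
#' diploid effective sizes and an ordered event list of population merges,
#' pulse admixtures (an admixed population is founded by two sources
#' contributing fractions r and 1-r of its ancestry), and size changes on
#' ancestral branches. Event times, sizes and rates may be numeric literals
#' or names of parameters bound to prior distributions (uniform or
#' log-uniform), optionally linked by order constraints (e.g.
#' `"t_admix < t_split"`). Scenario files are declarative YAML; see the
#' fixtures under `system.file("extdata", "scenarios", package = "radabc")`.
#'
#' @param x a list with entries `name`, `populations` (sampled population
#'   labels), optional `ghosts`, `ne` (deme -> size parameter/value),
#'   `events` (list of `{type: merge|admix|size, ...}` records),
#'   `priors`, optional `constraints`, `sample_sizes`, `missingness`,
#'   `point_estimates`, `trios`.
#' @return object of class `abc_scenario`
#' @export
scenario_from_list <- function(x) {
  stopifnot(!is.null(x$populations), !is.null(x$ne), !is.null(x$events))
  x$ghosts <- as.character(x$ghosts %||% character(0))
  demes <- c(x$populations, x$ghosts)
  if (anyDuplicated(demes)) stop("duplicated deme names")
  miss_ne <- setdiff(demes, names(x$ne))
  if (length(miss_ne)) stop("ne missing for: ", paste(miss_ne, collapse = ", "))
  for (ev in x$events) {
    type <- ev$type %||% stop("event without type")
    refs <- switch(type,
      merge = c(ev$source, ev$dest),
      admix = c(ev$target, ev$source1, ev$source2),
      size = ev$pop,
      stop("unknown event type: ", type))
    bad <- setdiff(refs, demes)
    if (length(bad)) stop("event references unknown deme(s): ",
                          paste(bad, collapse = ", "))
  }
  # every symbolic parameter used must be declared in the priors
  syms <- unlist(lapply(x$events, function(ev)
    Filter(is.character, ev[c("time", "rate", "size")])))
  syms <- c(syms, Filter(is.character, x$ne))
  undeclared <- setdiff(unique(unlist(syms)), names(x$priors))
  if (length(undeclared))
    stop("parameters without priors: ", paste(undeclared, collapse = ", "))
  sc <- structure(x, class = "abc_scenario")
  scenario_validate(sc)
  sc
}

#' @rdname scenario_from_list
#' @param path path to a scenario YAML file
#' @export
scenario_load <- function(path) scenario_from_list(yaml::read_yaml(path))

#' @export
print.abc_scenario <- function(x, ...) {
  cat(sprintf("abc_scenario '%s': %d sampled populations, %d ghost(s), %d events, %d parameters\n",
              x$name %||% "?", length(x$populations), length(x$ghosts),
              length(x$events), length(x$priors)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate that a scenario coalesces to a single root
#'
#' Replays the event list (at a representative parameter draw) checking that
#' every event references demes still alive at its time, and that exactly one
#' deme survives all merges/admixtures — i.e. all sampled lineages can reach
#' a common ancestor.
#'
#' @param sc an `abc_scenario`
#' @param params optional named parameter values (default: prior midpoints)
#' @return `TRUE`, invisibly; errors otherwise
#' @export
scenario_validate <- function(sc, params = NULL) {
  if (is.null(params)) {
    params <- vapply(sc$priors, function(pr) {
      if (identical(pr$dist, "loguniform")) exp(mean(log(c(pr$min, pr$max))))
      else mean(c(pr$min, pr$max))
    }, numeric(1))
  }
  demes <- c(sc$populations, sc$ghosts)
  alive <- setNames(rep(TRUE, length(demes)), demes)
  ev <- .build_events(sc, params, validate = FALSE)
  ord <- order(ev$time)
  for (i in ord) {
    e <- sc$events[[ev$orig[i]]]
    if (e$type == "merge") {
      if (!alive[e$source] || !alive[e$dest])
        stop("merge at t=", ev$time[i], " references a dead deme")
      alive[e$source] <- FALSE
    } else if (e$type == "admix") {
      if (!alive[e$target] || !alive[e$source1] || !alive[e$source2])
        stop("admixture at t=", ev$time[i], " references a dead deme")
      alive[e$target] <- FALSE
    } else if (!alive[e$pop]) {
      stop("size change at t=", ev$time[i], " on a dead deme")
    }
  }
  if (sum(alive) != 1)
    stop("scenario does not coalesce to a single root (",
         sum(alive), " branches remain)")
  invisible(TRUE)
}

# resolve a literal-or-parameter-name to a numeric value
.resolve <- function(v, params) {
  if (is.character(v)) {
    if (!v %in% names(params)) stop("unknown parameter: ", v)
    unname(params[[v]])
  } else as.numeric(v)
}

# build the numeric event table for the C++ core.
# columns: time, type(0/1/2), a, b, c, r, N -- deme indices are 0-based over
# c(populations, ghosts).
.build_events <- function(sc, params, validate = TRUE) {
  demes <- c(sc$populations, sc$ghosts)
  di <- function(x) match(x, demes) - 1L
  n <- length(sc$events)
  m <- matrix(0, n, 7)
  colnames(m) <- c("time", "type", "a", "b", "c", "r", "N")
  m[, "c"] <- -1
  for (i in seq_len(n)) {
    e <- sc$events[[i]]
    m[i, "time"] <- .resolve(e$time, params)
    if (e$type == "merge") {
      m[i, 2:5] <- c(0, di(e$source), di(e$dest), -1)
    } else if (e$type == "admix") {
      m[i, 2:5] <- c(1, di(e$target), di(e$source1), di(e$source2))
      m[i, "r"] <- .resolve(e$rate, params)
      if (validate && (m[i, "r"] <= 0 || m[i, "r"] > 1))
        stop("admixture rate must lie in (0,1]")
    } else {
      m[i, 2:3] <- c(2, di(e$pop))
      m[i, "N"] <- .resolve(e$size, params)
    }
  }
  ord <- order(m[, "time"])
  list(matrix = m[ord, , drop = FALSE], time = m[, "time"], orig = seq_len(n))
}

#' Draw parameter values from a scenario's priors
#'
#' Samples each declared parameter from its prior (uniform or log-uniform)
#' and applies the scenario's order constraints by rejection.
#'
#' @param sc an `abc_scenario`
#' @param n number of draws
#' @param max_tries rejection cap per draw; exceeding it signals an
#'   infeasible constraint set
#' @return data.frame with one row per draw, one column per parameter
#' @export
sample_prior <- function(sc, n = 1, max_tries = 1e5) {
  pn <- names(sc$priors)
  cons <- sc$constraints %||% character(0)
  draw1 <- function() {
    for (i in seq_len(max_tries)) {
      v <- vapply(sc$priors, function(pr) {
        d <- pr$dist %||% "uniform"
        if (d == "uniform") runif(1, pr$min, pr$max)
        else if (d == "loguniform") exp(runif(1, log(pr$min), log(pr$max)))
        else stop("unknown prior distribution: ", d)
      }, numeric(1))
      env <- as.list(v)
      ok <- all(vapply(cons, function(s)
        isTRUE(eval(parse(text = s), envir = env)), logical(1)))
      if (ok) return(v)
    }
    stop("prior constraints appear infeasible (rejection cap reached)")
  }
  out <- matrix(unlist(lapply(seq_len(n), function(i) draw1())),
                nrow = n, ncol = length(pn), byrow = TRUE,
                dimnames = list(NULL, pn))
  as.data.frame(out)
}

#' List the scenario fixture files shipped with the package
#' @return named character vector of YAML paths
#' @export
scenario_fixtures <- function() {
  dir <- system.file("extdata", "scenarios", package = "radabc")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  setNames(files, sub("\\.yaml$", "", basename(files)))
}
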