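#' Build a kinetic metabolic model
#'
#' A kinetic model is a reaction network with variable species (metabolites
#' whose concentrations follow the ODEs), boundary species (clamped
#' concentrations), and per-reaction kinetic parameters. Each reaction has a
#' stoichiometry over species and an infix rate-law expression over its own
#' parameters, the species, and the boundary species.
#'
#' @param species Named numeric vector: variable species initial
#'   concentrations (mM).
#' @param boundary Named numeric vector: clamped species concentrations.
#' @param reactions Named list; each element a list with \code{stoich}
#'   (named numeric over species/boundary; negatives consumed, positives
#'   produced), \code{rate} (character, infix expression), and \code{params}
#'   (named numeric, owned by this reaction).
#' @param name Optional model name.
#' @return An object of class \code{kinetic_model}.
#' @export
kinetic_model <- function(species, boundary = numeric(), reactions, name = "model") {
  stopifnot(is.numeric(species), !is.null(names(species)), length(reactions) > 0)
  if (length(boundary)) stopifnot(is.numeric(boundary), !is.null(names(boundary)))
  if (length(intersect(names(species), names(boundary)))) {
    stop("species and boundary names overlap", call. = FALSE)
  }
  all_sp <- c(names(species), names(boundary))
  for (rid in names(reactions)) {
    rx <- reactions[[rid]]
    if (is.null(rx$stoich) || is.null(rx$rate)) {
      stop("reaction ", rid, " lacks stoich or rate", call. = FALSE)
    }
    unknown <- setdiff(names(rx$stoich), all_sp)
    if (length(unknown)) {
      stop("reaction ", rid, ": undeclared species in stoichiometry: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    pn <- names(rx$params)
    syms <- all.vars(str2lang(rx$rate))
    bad <- setdiff(syms, c(all_sp, pn))
    if (length(bad)) {
      stop("reaction ", rid, ": undeclared symbol in rate law: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, species = species, boundary = boundary,
                 reactions = reactions), class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic model '%s': %d variable species, %d boundary, %d reactions, %d parameters\n",
              x$name, length(x$species), length(x$boundary), length(x$reactions),
              sum(vapply(x$reactions, function(r) length(r$params), 1L))))
  invisible(x)
}

#' Load a kinetic model from the native declarative YAML format
#'
#' The native format is a YAML document with keys \code{name},
#' \code{species} (map id -> initial concentration), \code{boundary}
#' (map id -> clamped concentration), and \code{reactions} (map id ->
#' \{stoich: map, rate: string, params: map\}). [write_model()] writes it
#' back; a write/read round trip is value-identical.
#'
#' @param path Path to a model file.
#' @return A \code{kinetic_model}.
#' @export
load_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species) || is.null(doc$reactions)) {
    stop("model file must declare `species` and `reactions`: ", path, call. = FALSE)
  }
  to_num <- function(x) {
    if (is.null(x)) return(numeric())
    stats::setNames(vapply(x, as.numeric, 1.0), names(x))
  }
  rxns <- lapply(doc$reactions, function(rx) {
    list(stoich = to_num(rx$stoich), rate = rx$rate, params = to_num(rx$params))
  })
  kinetic_model(species = to_num(doc$species), boundary = to_num(doc$boundary),
                reactions = rxns, name = if (is.null(doc$name)) "model" else doc$name)
}

#' Write a kinetic model in the native format
#'
#' @param model A \code{kinetic_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  doc <- list(
    name = model$name,
    species = as.list(model$species),
    boundary = as.list(model$boundary),
    reactions = lapply(model$reactions, function(rx) {
      list(stoich = as.list(rx$stoich), rate = rx$rate, params = as.list(rx$params))
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

# Compile the model into fast evaluators:
#  $flux(conc)  named flux vector
#  $dxdt(conc)  derivative of the variable species
#  $S           stoichiometric matrix (variable species x reactions)
compile_model <- function(model) {
  sp <- names(model$species)
  rids <- names(model$reactions)
  S <- matrix(0, length(sp), length(rids), dimnames = list(sp, rids))
  shared <- new.env(parent = baseenv())
  for (b in names(model$boundary)) assign(b, model$boundary[[b]], envir = shared)
  exprs <- vector("list", length(rids))
  envs <- vector("list", length(rids))
  for (k in seq_along(rids)) {
    rx <- model$reactions[[k]]
    st <- rx$stoich[names(rx$stoich) %in% sp]
    if (length(st)) S[names(st), k] <- st
    e <- new.env(parent = shared)
    for (p in names(rx$params)) assign(p, rx$params[[p]], envir = e)
    exprs[[k]] <- str2lang(rx$rate)
    envs[[k]] <- e
  }
  flux <- function(conc) {
    for (i in seq_along(sp)) assign(sp[i], conc[[i]], envir = shared)
    v <- vapply(seq_along(rids), function(k) eval(exprs[[k]], envs[[k]]), 1.0)
    names(v) <- rids
    v
  }
  dxdt <- function(conc) as.numeric(S %*% flux(conc))
  list(flux = flux, dxdt = dxdt, S = S, species = sp, reactions = rids)
}

#' Steady state of a kinetic model
#'
#' Solves \eqn{S v(x) = 0} for nonnegative concentrations by damped Newton
#' iteration (numeric Jacobian, step halving, max 200 steps) started from
#' the model's current concentrations, falling back to stiff time
#' integration (\code{deSolve::lsoda}) to \code{t_max} with a convergence
#' re-check. Failure to converge is a value (\code{converged = FALSE}),
#' never an error: the evolution loop discards such mutants.
#'
#' @param model A \code{kinetic_model}.
#' @param x0 Optional starting concentrations (defaults to
#'   \code{model$species}).
#' @param abs_tol Residual tolerance on max |dx/dt| (default 1e-9).
#' @param max_newton Maximum Newton steps (default 200).
#' @param t_max Fallback integration horizon in time units (default 1e6).
#' @param neg_tol Concentrations above \code{-neg_tol} are clipped to 0; more
#'   negative ones mean failure (default 1e-12).
#' @return List of class \code{steady_state}: \code{concentrations},
#'   \code{fluxes}, \code{converged}, \code{residual}, \code{method}.
#' @export
steady_state <- function(model, x0 = NULL, abs_tol = 1e-9, max_newton = 200,
                         t_max = 1e6, neg_tol = 1e-12) {
  cm <- compile_model(model)
  x <- if (is.null(x0)) as.numeric(model$species) else as.numeric(x0[cm$species])
  n <- length(x)

  finish <- function(x, method) {
    x[x < 0 & x > -neg_tol] <- 0
    f <- cm$dxdt(x)
    res <- max(abs(f))
    conv <- is.finite(res) && res < abs_tol && all(x >= 0)
    structure(list(concentrations = stats::setNames(x, cm$species),
                   fluxes = cm$flux(x), converged = conv, residual = res,
                   method = method), class = "steady_state")
  }

  # damped Newton
  f <- cm$dxdt(x)
  if (all(is.finite(f))) {
    for (it in seq_len(max_newton)) {
      nf <- sqrt(sum(f^2))
      if (max(abs(f)) < abs_tol * 0.1) break
      J <- numeric_jacobian(cm$dxdt, x, f)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) { f <- NULL; break }
      lam <- 1
      improved <- FALSE
      for (h in 1:30) {
        xn <- x + lam * step
        if (all(xn > -neg_tol)) {
          fn <- cm$dxdt(pmax(xn, 0))
          if (all(is.finite(fn)) && sqrt(sum(fn^2)) < nf) {
            x <- pmax(xn, 0); f <- fn; improved <- TRUE; break
          }
        }
        lam <- lam / 2
      }
      if (!improved) { f <- NULL; break }
    }
  } else f <- NULL

  if (!is.null(f) && max(abs(f)) < abs_tol) {
    ss <- finish(x, "newton")
    if (ss$converged) return(ss)
  }

  # fallback: stiff integration from the original start, then a Newton polish
  x <- if (is.null(x0)) as.numeric(model$species) else as.numeric(x0[cm$species])
  ode_fn <- function(t, y, parms) list(cm$dxdt(pmax(y, 0)))
  times <- c(0, 10^seq(0, log10(t_max), length.out = 12))
  sol <- tryCatch(
    suppressWarnings(deSolve::lsoda(y = x, times = times, func = ode_fn,
                                    parms = NULL, rtol = 1e-10, atol = 1e-12)),
    error = function(e) NULL)
  if (is.null(sol) || nrow(sol) < length(times) || anyNA(sol[nrow(sol), ])) {
    return(finish(pmax(x, 0), "failed"))
  }
  x <- pmax(as.numeric(sol[nrow(sol), -1L]), 0)
  f <- cm$dxdt(x)
  if (all(is.finite(f))) {
    for (it in seq_len(50)) {
      if (max(abs(f)) < abs_tol * 0.1) break
      J <- numeric_jacobian(cm$dxdt, x, f)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      xn <- x + step
      if (any(xn < -neg_tol)) break
      fn <- cm$dxdt(pmax(xn, 0))
      if (!all(is.finite(fn)) || sqrt(sum(fn^2)) >= sqrt(sum(f^2))) break
      x <- pmax(xn, 0); f <- fn
    }
  }
  finish(x, "integrate")
}

numeric_jacobian <- function(fn, x, f0 = NULL) {
  if (is.null(f0)) f0 <- fn(x)
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(1e-7 * abs(x[j]), 1e-10)
    xj <- x; xj[j] <- xj[j] + h
    J[, j] <- (fn(xj) - f0) / h
  }
  J
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state (%s): converged = %s, residual = %.3g\n",
              x$method, x$converged, x$residual))
  invisible(x)
}
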