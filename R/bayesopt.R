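#' Define a hyperparameter search dimension
#'
#' @param name Parameter name.
#' @param type `"num"` (uniform), `"lognum"` (log-uniform), `"int"`
#'   (uniform integer) or `"choice"` (unordered finite set).
#' @param lower,upper Bounds (ignored for `"choice"`).
#' @param values Candidate values for `"choice"`.
#' @return A `param_dim` list.
#' @export
param_dim <- function(name, type = c("num", "lognum", "int", "choice"),
                      lower = NULL, upper = NULL, values = NULL) {
  type <- match.arg(type)
  if (type == "choice") {
    if (length(values) < 1L) stop("choice dimension '", name, "' is empty")
  } else {
    if (is.null(lower) || is.null(upper) || lower >= upper) {
      stop("dimension '", name, "' needs lower < upper")
    }
    if (type == "lognum" && lower <= 0) stop("lognum dimension needs lower > 0")
  }
  structure(list(name = name, type = type, lower = lower, upper = upper,
                 values = values), class = "param_dim")
}

decode_point <- function(space, u) {
  out <- list()
  for (i in seq_along(space)) {
    d <- space[[i]]
    out[[d$name]] <- switch(d$type,
      num    = d$lower + u[i] * (d$upper - d$lower),
      lognum = exp(log(d$lower) + u[i] * (log(d$upper) - log(d$lower))),
      int    = as.integer(round(d$lower + u[i] * (d$upper - d$lower))),
      choice = d$values[[1L + min(length(d$values) - 1L,
                                  floor(u[i] * length(d$values)))]])
  }
  out
}

# squared-exponential GP posterior on [0,1]^d with fixed length-scale
gp_posterior <- function(U, y, Unew, lengthscale = 0.25, nugget = 1e-6) {
  s2 <- max(stats::var(y), 1e-12)
  sqd <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, `+`) - 2 * A %*% t(B), 0)
  }
  K <- s2 * exp(-sqd(U, U) / (2 * lengthscale^2)) + diag(s2 * nugget, nrow(U))
  Ks <- s2 * exp(-sqd(Unew, U) / (2 * lengthscale^2))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mean(y)))
  mu <- mean(y) + drop(Ks %*% alpha)
  V <- forwardsolve(t(L), t(Ks))
  var <- pmax(s2 - colSums(V^2), 1e-12)
  list(mean = mu, sd = sqrt(var))
}

#' Sequential model-based (Bayesian) optimization
#'
#' Gaussian-process surrogate (squared-exponential kernel on the unit-cube
#' encoding of the mixed space) with expected-improvement acquisition;
#' begins from a Latin-hypercube design. Objectives returning non-finite
#' values are recorded as failures and skipped by the surrogate. With
#' `method = "random"` the optimizer degrades to pure random search over
#' the same encoding.
#'
#' @param objective Function taking a named list of decoded parameters and
#'   returning a scalar to minimize (e.g. validation classification error).
#' @param space List of [param_dim()]s.
#' @param budget Total number of objective evaluations (>= 1).
#' @param seed Integer seed.
#' @param n_init Initial design size (default `min(budget, max(4, d + 1))`).
#' @param method `"gp"` or `"random"`.
#' @return List: `best` (decoded named list), `best_value`, `trace` (data
#'   frame with the encoded coordinates, decoded values, objective and
#'   failure flag).
#' @export
bayes_optimize <- function(objective, space, budget = 15L, seed = 1L,
                           n_init = NULL, method = c("gp", "random")) {
  method <- match.arg(method)
  stopifnot(budget >= 1L, length(space) >= 1L)
  d <- length(space)
  if (is.null(n_init)) n_init <- min(budget, max(4L, d + 1L))
  set.seed(as.integer(seed))
  U <- matrix(NA_real_, budget, d)
  U[seq_len(n_init), ] <- lhs::maximinLHS(n_init, d)
  y <- rep(NA_real_, budget)
  failed <- rep(FALSE, budget)
  decoded <- vector("list", budget)
  for (it in seq_len(budget)) {
    if (it > n_init) {
      ok <- which(!failed[seq_len(it - 1L)])
      cand <- matrix(stats::runif(512L * d), ncol = d)
      if (method == "gp" && length(ok) >= 2L &&
          stats::sd(y[ok]) > 0) {
        post <- gp_posterior(U[ok, , drop = FALSE], y[ok], cand)
        ymin <- min(y[ok])
        xi <- 0.01 * stats::sd(y[ok])
        z <- (ymin - post$mean - xi) / post$sd
        ei <- (ymin - post$mean - xi) * stats::pnorm(z) + post$sd * stats::dnorm(z)
        U[it, ] <- cand[which.max(ei), ]
      } else {
        U[it, ] <- cand[1L, ]
      }
    }
    decoded[[it]] <- decode_point(space, U[it, ])
    val <- tryCatch(objective(decoded[[it]]), error = function(e) NA_real_)
    if (!is.finite(val)) {
      failed[it] <- TRUE
      y[it] <- NA_real_
    } else {
      y[it] <- val
    }
  }
  if (all(failed)) stop("all ", budget, " objective evaluations failed")
  best_i <- which.min(ifelse(failed, Inf, y))
  trace <- data.frame(iteration = seq_len(budget), objective = y,
                      failed = failed)
  for (j in seq_len(d)) {
    trace[[space[[j]]$name]] <- vapply(decoded, function(p) {
      v <- p[[space[[j]]$name]]
      if (is.numeric(v)) v else NA_real_
    }, 1)
  }
  list(best = decoded[[best_i]], best_value = y[best_i], trace = trace)
}

#' Default CNN hyperparameter space
#'
#' Section depth 1-3, log-uniform learning rate and L2 strength, momentum
#' interval, kernel sizes \{3, 5, 7\} and 4-16 first-block filters.
#'
#' @return List of [param_dim()]s.
#' @export
default_cnn_space <- function() {
  list(param_dim("section_depth", "int", 1, 3),
       param_dim("learning_rate", "lognum", 1e-3, 1e-1),
       param_dim("momentum", "num", 0.5, 0.95),
       param_dim("l2", "lognum", 1e-6, 1e-3),
       param_dim("filter_size", "choice", values = c(3L, 5L, 7L)),
       param_dim("n_filters", "int", 4, 16))
}
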