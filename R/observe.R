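#' Sample noisy replicate observations from a simulated reactor
#'
#' Emulates the weekly porewater monitoring of the reactors: on each
#' scheduled day, `n_reps` independent measurements of each analyte are
#' drawn around the latent value (additive Gaussian noise, truncated at
#' zero) and summarised as replicate mean, sample SD (n-1 denominator;
#' reported as 0 when `n_reps = 1`) and n.
#'
#' Noise SDs are given per analyte in the analyte's native reporting unit:
#' sulfate in mM, sulfide and ferrous iron in uM.
#'
#' @param sim a [simulate_reactor()] result
#' @param schedule sampling days (within the simulated duration)
#' @param noise_sd named numeric vector of per-analyte measurement SDs,
#'   e.g. `c(sulfate = 0.5, sulfide = 10, fe = 5)`
#' @param n_reps replicates per sampling day (default 3)
#' @param seed integer seed
#' @return a `porewater_series` data.frame with columns day, analyte,
#'   mean, sd, n
#' @export
sample_observations <- function(sim, schedule,
                                noise_sd = c(sulfate = 0.5, sulfide = 10, fe = 5),
                                n_reps = 3, seed = 1L) {
  stopifnot(inherits(sim, "reactor_sim"))
  if (any(schedule < 0 | schedule > sim$config$duration)) {
    stop("'schedule' days must lie within the simulated duration", call. = FALSE)
  }
  if (n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  analytes <- c("sulfate", "sulfide", "fe")
  miss <- setdiff(analytes, names(noise_sd))
  if (length(miss)) {
    stop("'noise_sd' must name all of: ", paste(analytes, collapse = ", "),
         call. = FALSE)
  }
  assert_nonneg(noise_sd, "noise_sd")

  traj <- sim$trajectory
  set.seed(as.integer(seed))
  out <- vector("list", length(analytes))
  for (i in seq_along(analytes)) {
    an <- analytes[i]
    latent <- stats::approx(traj$day, traj[[an]], xout = schedule)$y
    m <- s <- numeric(length(schedule))
    for (j in seq_along(schedule)) {
      reps <- pmax(0, latent[j] + stats::rnorm(n_reps, 0, noise_sd[[an]]))
      m[j] <- mean(reps)
      s[j] <- if (n_reps > 1) stats::sd(reps) else 0
    }
    out[[i]] <- data.frame(day = schedule, analyte = an, mean = m, sd = s,
                           n = as.integer(n_reps))
  }
  porewater_series(do.call(rbind, out))
}

#' Construct / validate a porewater monitoring series
#'
#' A long-format record of replicate-summarised porewater chemistry:
#' one row per sampling day and analyte, with replicate mean, sample SD
#' and replicate count. Days must be strictly increasing within each
#' analyte.
#'
#' @param x data.frame with columns day, analyte, mean, sd, n
#' @return the validated data.frame with class `porewater_series`
#' @export
porewater_series <- function(x) {
  need <- c("day", "analyte", "mean", "sd", "n")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("a porewater series needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$n < 1)) stop("'n' must be >= 1", call. = FALSE)
  if (any(x$sd < 0)) stop("'sd' must be >= 0", call. = FALSE)
  for (an in unique(x$analyte)) {
    d <- x$day[x$analyte == an]
    if (any(diff(d) <= 0)) {
      stop(sprintf("days must be strictly increasing within analyte '%s'", an),
           call. = FALSE)
    }
  }
  class(x) <- unique(c("porewater_series", class(x)))
  x
}
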