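#' Mechanical parameter set for the spreading-tissue model
#'
#' Bundles the four inferable parameters of the Eulerian continuum model of
#' explant spreading. The edge force `F`, stiffness `k` and adhesion `b`
#' enter the governing equations only through the ratios `F/k` and `k/b`,
#' so only the ratios are represented.
#'
#' @param F_over_k Dimensionless ratio of the net outward lamellipodia force
#'   per unit edge length to the residual stretching modulus of the tissue.
#' @param k_over_b Effective diffusivity of tissue density
#'   (stiffness over substrate adhesion), in um^2/h.
#' @param alpha Visible material growth rate due to radial intercalation or
#'   active cell shape change, in 1/h.
#' @param rho_unstressed Density of relaxed tissue at mechanical equilibrium,
#'   in cells/mm^2 (see [model_config()] for the unit convention).
#'
#' @return An object of class `parameter_set`: a named list with the four
#'   fields above.
#' @examples
#' theta <- parameter_set(0.8, 1000, 0.5, 1500)
#' boundary_density(theta)
#' @export
parameter_set <- function(F_over_k, k_over_b, alpha, rho_unstressed) {
  p <- list(
    F_over_k = as.numeric(F_over_k),
    k_over_b = as.numeric(k_over_b),
    alpha = as.numeric(alpha),
    rho_unstressed = as.numeric(rho_unstressed)
  )
  class(p) <- "parameter_set"
  validate_parameter_set(p)
  p
}

validate_parameter_set <- function(p) {
  vals <- unlist(p[c("F_over_k", "k_over_b", "alpha", "rho_unstressed")])
  if (length(vals) != 4L || !all(is.finite(vals)))
    stop("parameter_set: all four fields must be finite numbers", call. = FALSE)
  if (p$F_over_k < 0) stop("parameter_set: F_over_k must be >= 0", call. = FALSE)
  if (p$k_over_b <= 0) stop("parameter_set: k_over_b must be > 0", call. = FALSE)
  if (p$alpha < 0) stop("parameter_set: alpha must be >= 0", call. = FALSE)
  if (p$rho_unstressed <= 0)
    stop("parameter_set: rho_unstressed must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf(
    "parameter_set: F/k = %.4g, k/b = %.4g um^2/h, alpha = %.4g 1/h, rho_unstressed = %.4g cells/mm^2\n",
    x$F_over_k, x$k_over_b, x$alpha, x$rho_unstressed
  ))
  invisible(x)
}

#' Uniform prior bounds for the model parameters
#'
#' Independent uniform priors U(a, b) for each parameter. The defaults are the
#' broad bounds used for explant fitting: F/k ~ U(0, 1.5), k/b ~ U(500, 5000)
#' um^2/h, alpha ~ U(0, 1) 1/h, rho_unstressed ~ U(1000, 2000).
#'
#' @param F_over_k,k_over_b,alpha,rho_unstressed Numeric length-2 vectors
#'   `c(a, b)` with `a < b`.
#' @return An object of class `prior_spec`.
#' @examples
#' pr <- prior_spec()
#' sample_prior(pr)
#' @export
prior_spec <- function(F_over_k = c(0, 1.5),
                       k_over_b = c(500, 5000),
                       alpha = c(0, 1),
                       rho_unstressed = c(1000, 2000)) {
  pr <- list(
    F_over_k = as.numeric(F_over_k),
    k_over_b = as.numeric(k_over_b),
    alpha = as.numeric(alpha),
    rho_unstressed = as.numeric(rho_unstressed)
  )
  for (nm in names(pr)) {
    b <- pr[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop(sprintf("prior_spec: bounds for %s must be c(a, b) with a < b", nm),
           call. = FALSE)
  }
  class(pr) <- "prior_spec"
  pr
}

#' Simulation configuration
#'
#' Fixed (non-inferred) model settings. The canonical density unit is
#' cells/mm^2: the initial interior density is 0.0047 cells/um^2, i.e. 4700
#' cells/mm^2, and prior values for `rho_unstressed` are interpreted in
#' cells/mm^2. `density_unit_scale` multiplies `rho_unstressed` before use in
#' the governing equations, letting a user restore a different convention
#' (e.g. `density_unit_scale = 1` with `rho_init` given in the same unit).
#'
#' @param rho_init Initial interior density, cells/mm^2. Default 4700.
#' @param mass_cap_fraction Fraction of the initial visible mass after which
#'   material addition shuts off. Default 0.5 (at most 50% more cells appear
#'   in the visible layer).
#' @param density_unit_scale Factor applied to `rho_unstressed` to map prior
#'   values into simulation density units. Default 1.
#' @return An object of class `model_config`.
#' @export
model_config <- function(rho_init = 4700,
                         mass_cap_fraction = 0.5,
                         density_unit_scale = 1) {
  if (!is.finite(rho_init) || rho_init <= 0)
    stop("model_config: rho_init must be > 0", call. = FALSE)
  if (!is.finite(mass_cap_fraction) || mass_cap_fraction <= 0 ||
      mass_cap_fraction > 1)
    stop("model_config: mass_cap_fraction must be in (0, 1]", call. = FALSE)
  if (!is.finite(density_unit_scale) || density_unit_scale <= 0)
    stop("model_config: density_unit_scale must be > 0", call. = FALSE)
  structure(
    list(rho_init = rho_init, mass_cap_fraction = mass_cap_fraction,
         density_unit_scale = density_unit_scale),
    class = "model_config"
  )
}

# Effective unstressed density in simulation units.
rho_u_sim <- function(params, config) {
  params$rho_unstressed * config$density_unit_scale
}

#' Tissue density imposed at the moving edge
#'
#' At the free edge the tissue is stretched by the lamellipodia force, so its
#' density there is pinned at `rho_unstressed * exp(-F/k)` (a Dirichlet
#' boundary condition on the moving interface).
#'
#' @param params A [parameter_set()].
#' @param config A [model_config()] (supplies the density unit scale).
#' @return Edge density, cells/mm^2. Always positive and at most
#'   `rho_unstressed`.
#' @export
boundary_density <- function(params, config = model_config()) {
  validate_parameter_set(params)
  rho_u_sim(params, config) * exp(-params$F_over_k)
}

#' Limiting (compressed) tissue density
#'
#' The density-dependent material addition term saturates at
#' `rho_unstressed * exp(F/k)`, the density of a fully compressed tissue.
#'
#' @inheritParams boundary_density
#' @return Limiting density, cells/mm^2. Always at least `rho_unstressed`.
#' @export
limiting_density <- function(params, config = model_config()) {
  validate_parameter_set(params)
  rho_u_sim(params, config) * exp(params$F_over_k)
}

#' Mass-limited logistic growth of visible material
#'
#' Rate of visible-material addition (radial intercalation / cell shape
#' change): logistic in the local density, `alpha * rho * (1 - rho/rho_lim)`,
#' shut off entirely once the cumulative added mass `m` reaches
#' `mass_cap_fraction * m0` (inclusive). The logistic term is applied
#' literally and may be negative where `rho > rho_lim`.
#'
#' @param rho Local density (scalar or array), cells/mm^2.
#' @param m Cumulative added visible mass so far, cells.
#' @param m0 Initial visible mass, cells.
#' @inheritParams boundary_density
#' @return Density rate of change, cells/mm^2/h, same shape as `rho`.
#' @export
growth_rate <- function(rho, m, m0, params, config = model_config()) {
  if (!is.finite(m) || m < 0) stop("growth_rate: m must be >= 0", call. = FALSE)
  if (!is.finite(m0) || m0 <= 0) stop("growth_rate: m0 must be > 0", call. = FALSE)
  if (m >= config$mass_cap_fraction * m0) {
    return(rho * 0)
  }
  rho_lim <- limiting_density(params, config)
  params$alpha * rho * (1 - rho / rho_lim)
}

#' Normal velocity of the tissue edge
#'
#' The free edge advances at
#' `-(k/b) * exp(F/k) / rho_unstressed * (grad rho . n)`, where `n` is the
#' outward normal: an interior density above the edge density (negative
#' outward gradient) drives outward spreading.
#'
#' @param grad_rho_normal Density gradient along the outward normal,
#'   cells/mm^2/um (scalar or array).
#' @inheritParams boundary_density
#' @return Normal speed, um/h (positive = outward).
#' @export
boundary_normal_velocity <- function(grad_rho_normal, params,
                                     config = model_config()) {
  validate_parameter_set(params)
  -params$k_over_b * exp(params$F_over_k) * grad_rho_normal /
    rho_u_sim(params, config)
}

#' Draw one parameter set from the prior
#'
#' Each parameter is drawn independently and uniformly from its bounds, using
#' R's current RNG stream (seed with `set.seed()` for reproducibility).
#'
#' @param priors A [prior_spec()].
#' @return A [parameter_set()].
#' @export
sample_prior <- function(priors = prior_spec()) {
  if (!inherits(priors, "prior_spec")) stop("sample_prior: need a prior_spec")
  draw <- function(b) stats::runif(1, b[1], b[2])
  parameter_set(
    F_over_k = draw(priors$F_over_k),
    k_over_b = draw(priors$k_over_b),
    alpha = draw(priors$alpha),
    rho_unstressed = draw(priors$rho_unstressed)
  )
}

#' Read/write parameter and prior configuration files
#'
#' `parameter_set` and `prior_spec` round-trip through flat key-value JSON or
#' YAML files with exactly the field names of the objects; units are um, h,
#' cells/mm^2 throughout.
#'
#' @param x A `parameter_set` or `prior_spec`.
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `write_config` returns `path` invisibly; `read_parameter_set` and
#'   `read_prior_spec` return the reconstructed object.
#' @export
write_config <- function(x, path) {
  lst <- unclass(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path)
  } else stop("write_config: unsupported extension: ", ext, call. = FALSE)
  invisible(path)
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("read_config: unsupported extension: ", ext, call. = FALSE)
}

#' @rdname write_config
#' @export
read_parameter_set <- function(path) {
  lst <- read_config_file(path)
  parameter_set(lst$F_over_k, lst$k_over_b, lst$alpha, lst$rho_unstressed)
}

#' @rdname write_config
#' @export
read_prior_spec <- function(path) {
  lst <- read_config_file(path)
  prior_spec(unlist(lst$F_over_k), unlist(lst$k_over_b),
             unlist(lst$alpha), unlist(lst$rho_unstressed))
}
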