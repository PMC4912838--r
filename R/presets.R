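.preset_names <- c("NC", "HP", "ind", "cor2", "fig1bc", "fig2ab", "fig2cd",
                   "fig3a", "fig3b", "fig4", "fig2s1")

#' Named presynaptic-statistics presets
#'
#' Returns the parameter set of one of the named input-statistics presets.
#' `"NC"` reproduces neocortical population activity during quiet wakefulness
#' (up/down-state switching), `"HP"` hippocampal sharp-wave dynamics, `"ind"`
#' independent presynaptic neurons, and `"cor2"` purely second-order
#' (equicorrelated Gaussian) correlations with free correlation `rho`. The
#' per-figure presets (`fig1bc`, `fig2ab`, `fig2cd`, `fig3a`, `fig3b`, `fig4`,
#' `fig2s1`) reproduce the demonstration scenarios used throughout the
#' package: `fig1bc` is an assembly of `n_neurons` singleton groups (each
#' neuron has its own private state, so neurons are mutually independent),
#' `fig4` is four independent ten-neuron assemblies, and `fig2s1` is the
#' single-neuron configuration used to validate the filter against a particle
#' filter.
#'
#' Each returned object carries attributes `tau_post` (ms) and `weights`
#' (default \eqn{w_i = 1/N}) giving the readout configuration conventionally
#' used with that preset.
#'
#' @param name preset name, one of `r paste0('"', .preset_names, '"', collapse = ", ")`.
#' @param n_neurons override the preset's neuron count (for `ind`, `cor2`,
#'   `fig1bc`).
#' @param rho pairwise correlation for `cor2` (default 0.5); must be
#'   \eqn{\ge -1/(N-1)}.
#' @return [population_params()] or [assembly_population()] with attributes
#'   `tau_post` and `weights`.
#' @export
load_preset <- function(name, n_neurons = NULL, rho = NULL) {
  if (!is.character(name) || length(name) != 1 || !(name %in% .preset_names))
    stop("unknown preset '", name, "'; valid presets are: ",
         paste(.preset_names, collapse = ", "))
  pp <- function(N, omp, omm, ubar, sii, sij, g, beta, refr, prel, tau = 20) {
    S <- sii * diag(N)
    if (N > 1) S[S == 0] <- sij
    population_params(N, omp, omm, ubar, tau, S, g, beta, refr, prel)
  }
  deco <- function(x, tau_post, N) {
    attr(x, "tau_post") <- tau_post
    attr(x, "weights") <- rep(1 / N, N)
    attr(x, "preset") <- name
    x
  }
  switch(name,
    NC = {
      N <- if (is.null(n_neurons)) 10L else n_neurons
      deco(pp(N, 4, 10, 10, 10, 5, 1, 0.1, 3, 0.5), 0, N)
    },
    HP = {
      N <- if (is.null(n_neurons)) 10L else n_neurons
      deco(pp(N, 0.027, 10, 2.3, 1, 0.5, 2, 0.6, 3, 0.2), 0, N)
    },
    ind = {
      N <- if (is.null(n_neurons)) 10L else n_neurons
      deco(pp(N, 0, 0, 0, 1, 0, 0.5, 1, 3, 1), 0, N)
    },
    cor2 = {
      N <- if (is.null(n_neurons)) 10L else n_neurons
      r <- if (is.null(rho)) 0.5 else rho
      S <- equicorr_cov(N, 1, r)
      p <- population_params(N, 0, 0, 0, 20, S, 0.5, 2, 3, 1)
      deco(p, 0, N)
    },
    fig1bc = {
      N <- if (is.null(n_neurons)) 20L else n_neurons
      g1 <- pp(1L, 10, 10, 2.4, 1, 0, 1, 1, 3, 1)
      deco(assembly_population(rep(list(g1), N)), 0, N)
    },
    fig2ab = deco(pp(70L, 0, 0, 0, 16, 0.5, 1, 0.4, 3, 1), 10, 70L),
    fig2cd = deco(pp(20L, 0.27, 10, 2.3, 4, 0.5, 1, 0.4, 3, 1), 10, 20L),
    fig3a  = deco(pp(10L, 0.67, 10, 2.3, 1, 0, 5.3, 0.5, 1, 1), 0, 10L),
    fig3b  = deco(pp(10L, 0, 0, 0, 1, 0.5, 0.5, 0.4, 3, 1), 0, 10L),
    fig4 = {
      g <- pp(10L, 0.67, 10, 2.3, 1, 0, 5, 0.4, 1, 1)
      deco(assembly_population(rep(list(g), 4)), 0, 40L)
    },
    fig2s1 = deco(pp(1L, 5, 5, 5, 4, 0, 10, 0.33, 0, 1), 0, 1L)
  )
}
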