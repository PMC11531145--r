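#' Fit the full 16-model factor lattice
#'
#' Fits every model of [model_lattice()] with a shared seed and latent
#' dimension, so log-likelihoods are comparable across models.
#'
#' @param design A `jsdm_design`.
#' @param r Latent-factor dimension for covariance models.
#' @param seed Integer seed shared across fits.
#' @param control A [jsdm_control()].
#' @param models Optional subset of model names to fit (default: all 16).
#' @return An object of class `jsdm_lattice`: a tibble with the model
#'   columns of [model_lattice()] plus `ll`, `auc` and a `fit` list-column.
#' @export
fit_lattice <- function(design, r = 8, seed = 1, control = jsdm_control(),
                        models = NULL) {
  lat <- model_lattice()
  if (!is.null(models)) {
    stopifnot(all(models %in% lat$name))
    lat <- lat[lat$name %in% models, ]
  }
  fits <- lapply(seq_len(nrow(lat)), function(i)
    jsdm_fit(design, lat[i, ], r = r, seed = seed, control = control))
  lat$ll <- vapply(fits, `[[`, numeric(1), "ll_total")
  lat$auc <- vapply(fits, roc_auc, numeric(1))
  lat$fit <- fits
  structure(lat, class = c("jsdm_lattice", class(lat)))
}

#' The five models needed for factor attribution
#'
#' Convenience wrapper around [fit_lattice()] fitting only the full model
#' and the four three-factor/two-factor comparators used by
#' [attribute_factors()].
#'
#' @inheritParams fit_lattice
#' @return A `jsdm_lattice` with five rows.
#' @export
fit_attribution_models <- function(design, r = 8, seed = 1,
                                   control = jsdm_control()) {
  fit_lattice(design, r = r, seed = seed, control = control,
              models = c("Full (P + S + Sp + Cov)", "P + S + Sp",
                         "S + Sp", "P + Sp", "P + S"))
}

#' Per-OTU log-likelihood ratio between two fitted models
#'
#' @param fit_a,fit_b `jsdm_fit` objects over the same response.
#' @return A named numeric vector, one LLR per OTU; its sum equals the total
#'   log-likelihood ratio.
#' @export
per_otu_llr <- function(fit_a, fit_b) {
  stopifnot(identical(fit_a$otu_ids, fit_b$otu_ids))
  fit_a$ll_per_otu - fit_b$ll_per_otu
}

# The four comparisons: the covariance effect is judged against the full
# model; plant, soil and space are judged against the covariance-free model
# so that factor effects are not absorbed into shared-niche covariance.
attribution_pairs <- function() {
  tibble::tribble(
    ~factor, ~model_a,                  ~model_b,
    "P",     "P + S + Sp",              "S + Sp",
    "S",     "P + S + Sp",              "P + Sp",
    "Sp",    "P + S + Sp",              "P + S",
    "Cov",   "Full (P + S + Sp + Cov)", "P + S + Sp")
}

#' Attribute per-OTU explanatory power to the four assembly factors
#'
#' For each factor the per-OTU log-likelihood ratio between the designated
#' model pair is computed (see `attribution_pairs()` in the source: P, S and
#' Sp are evaluated by dropping the factor from the covariance-free
#' three-factor model; Cov by comparing the full model with the
#' covariance-free model). When a guild map is supplied, guilds with at
#' least `min_guild_size` OTUs are compared by Steel-Dwass tests.
#'
#' @param lattice A `jsdm_lattice` containing the five required models.
#' @param guilds Optional tibble with `otu_id`, `guild`.
#' @param min_guild_size Minimum OTUs for a guild to enter the tests.
#' @return An object of class `factor_attribution`: list with `llr` (tibble:
#'   otu_id, factor, llr, guild), `pairs` (the comparisons used) and
#'   `guild_tests` (per-factor Steel-Dwass results, if guilds given).
#' @export
attribute_factors <- function(lattice, guilds = NULL, min_guild_size = 5) {
  pairs <- attribution_pairs()
  need <- unique(c(pairs$model_a, pairs$model_b))
  miss <- setdiff(need, lattice$name)
  if (length(miss) > 0)
    stop("lattice lacks model(s): ", paste(miss, collapse = ", "))
  get_fit <- function(nm) lattice$fit[[which(lattice$name == nm)]]
  llr <- purrr::pmap_dfr(pairs, function(factor, model_a, model_b) {
    v <- per_otu_llr(get_fit(model_a), get_fit(model_b))
    tibble::tibble(otu_id = names(v), factor = factor, llr = unname(v))
  })
  guild_tests <- NULL
  if (!is.null(guilds)) {
    llr$guild <- guilds$guild[match(llr$otu_id, guilds$otu_id)]
    guild_tests <- lapply(split(llr, llr$factor), function(d) {
      tryCatch(steel_dwass(d$llr, d$guild, min_group_size = min_guild_size),
               error = function(e) NULL)
    })
  }
  structure(list(llr = llr, pairs = pairs, guild_tests = guild_tests),
            class = "factor_attribution")
}

#' @export
print.factor_attribution <- function(x, ...) {
  cat("Factor attribution (per-OTU log-likelihood ratios)\n")
  s <- dplyr::summarise(dplyr::group_by(x$llr, .data$factor),
                        median_llr = stats::median(.data$llr), .groups = "drop")
  print(s)
  invisible(x)
}
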