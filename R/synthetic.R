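#' Ground-truth parameters for synthetic root/soil datasets
#'
#' Defines the generative conditions a synthetic dataset emulates: the
#' sampling design (positions at least `min_spacing` metres apart, several
#' root-tip samples per position labelled with a host-plant genus, one soil
#' sample per position), guild-specific assembly effects, and overdispersed
#' sequencing depths.
#'
#' Guild effect scales are given per guild archetype: `plant_effect_sd`
#' (host-filtering strength, probit scale), `soil_coupling` (weight of the
#' OTU's own latent soil field), `spatial_effect_sd` (weight of an
#' OTU-specific spatial field), `factor_loading_sd` (residual fungus-fungus
#' covariance via latent factors), and `spatial_range` (metres, exponential
#' covariance range of the Gaussian-process fields).
#'
#' @param n_positions Number of sampling positions (default 124).
#' @param min_spacing Minimum distance between positions in metres.
#' @param arena Side length (metres) of the square sampling arena.
#' @param plants Character vector of host-plant genus labels.
#' @param mean_samples_per_position Mean root-tip samples per position.
#' @param guild_effects Data frame with columns `guild`, `n_otus`,
#'   `plant_effect_sd`, `soil_coupling`, `spatial_effect_sd`,
#'   `factor_loading_sd`, `spatial_range`.
#' @param n_latent_factors Latent-factor dimension of the residual
#'   covariance in the generative probit model.
#' @param alpha_mean,alpha_sd Mean and SD of per-OTU probit intercepts.
#' @param root_depth_mean,root_depth_size Negative-binomial read-depth model
#'   for root samples.
#' @param soil_depth_mean,soil_depth_size Depth model for soil samples.
#' @param n_soil_extra_otus Soil-only OTUs added to the soil table.
#' @param plant_clump_range Metres; spatial clumping range of host genera.
#' @param fixed_effort Use exactly `mean_samples_per_position` root samples
#'   at every position (instead of Poisson counts). Constant effort keeps
#'   position-level pooled communities exchangeable, which the calibration
#'   preset relies on.
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(n_positions = 124,
                         min_spacing = 4,
                         arena = 280,
                         plants = c("Pinus", "Betula", "Quercus", "Populus", "Castanea",
                                    "Corylus", "Acer", "Larix", "Juglans", "Fagus"),
                         mean_samples_per_position = 12,
                         guild_effects = default_guild_effects(),
                         n_latent_factors = 2,
                         alpha_mean = -0.8, alpha_sd = 0.5,
                         root_depth_mean = 2e4, root_depth_size = 2,
                         soil_depth_mean = 1e5, soil_depth_size = 2,
                         n_soil_extra_otus = 20,
                         plant_clump_range = 60,
                         fixed_effort = FALSE) {
  stopifnot(n_positions >= 2, min_spacing > 0, arena > 0,
            all(guild_effects$spatial_range > 0),
            all(guild_effects[, c("plant_effect_sd", "soil_coupling",
                                  "spatial_effect_sd", "factor_loading_sd")] >= 0))
  structure(list(n_positions = n_positions, min_spacing = min_spacing,
                 arena = arena, plants = plants,
                 mean_samples_per_position = mean_samples_per_position,
                 guild_effects = guild_effects,
                 n_latent_factors = n_latent_factors,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 root_depth_mean = root_depth_mean, root_depth_size = root_depth_size,
                 soil_depth_mean = soil_depth_mean, soil_depth_size = soil_depth_size,
                 n_soil_extra_otus = n_soil_extra_otus,
                 plant_clump_range = plant_clump_range,
                 fixed_effort = fixed_effort),
            class = "truth_params")
}

#' Default guild archetypes for the synthetic generator
#'
#' Three archetypes mirror the contrasting assembly modes of the major
#' root-associated guilds: EcMF-like OTUs couple strongly to the background
#' soil community and are spatially structured; Endophyte-like OTUs depend
#' mostly on residual fungus-fungus covariance; AMF-like OTUs are strongly
#' host-filtered. EcMF plant filtering is set to zero so host-effect recovery
#' can be scored against a known no-effect group.
#'
#' @return A data frame of guild effect scales.
#' @export
default_guild_effects <- function() {
  data.frame(
    guild            = c("EcMF", "Endophyte", "AMF"),
    n_otus           = c(16L, 14L, 10L),
    plant_effect_sd  = c(0.0, 0.8, 1.5),
    soil_coupling    = c(1.2, 0.1, 0.3),
    spatial_effect_sd = c(1.0, 0.2, 0.5),
    factor_loading_sd = c(0.4, 1.5, 0.4),
    spatial_range    = c(10, 10, 10))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate sampling positions and host-plant assignments
#'
#' Positions are placed on a jittered grid with rejection so that all
#' pairwise distances are at least `min_spacing`. Each position carries one
#' to three host-plant genera (drawn with spatially clumped probabilities)
#' and a per-genus root-sample count.
#'
#' @param params A `truth_params` object.
#' @param seed Integer seed.
#' @return A list with `positions` (tibble: position_id, x, y) and
#'   `root_plan` (tibble: position_id, host_plant, n_samples).
#' @export
generate_landscape <- function(params, seed = 1) {
  with_seed(seed, {
    n <- params$n_positions
    k <- ceiling(sqrt(n))
    cell <- params$arena / k
    if (cell <= params$min_spacing)
      stop("cannot place ", n, " positions at ", params$min_spacing,
           "-m spacing; use a larger arena")
    jit <- (cell - params$min_spacing) / 2
    for (try in 1:50) {
      centers <- expand.grid(ix = seq_len(k), iy = seq_len(k))
      centers <- centers[sample.int(nrow(centers), n), ]
      x <- (centers$ix - 0.5) * cell + stats::runif(n, -jit, jit)
      y <- (centers$iy - 0.5) * cell + stats::runif(n, -jit, jit)
      if (n < 2 || min(stats::dist(cbind(x, y))) >= params$min_spacing) break
      if (try == 50) stop("cannot satisfy spacing; use a larger arena")
    }
    positions <- tibble::tibble(
      position_id = sprintf("pos%03d", seq_len(n)), x = x, y = y)
    # spatially clumped host-genus weights
    np <- length(params$plants)
    cx <- stats::runif(np, 0, params$arena); cy <- stats::runif(np, 0, params$arena)
    ab <- stats::rexp(np) + 0.2    # uneven genus frequencies
    plan <- vector("list", n)
    for (i in seq_len(n)) {
      d2 <- (positions$x[i] - cx)^2 + (positions$y[i] - cy)^2
      w <- ab * (exp(-d2 / (2 * params$plant_clump_range^2)) + 0.1)
      n_gen <- sample(1:3, 1, prob = c(0.45, 0.4, 0.15))
      n_gen <- min(n_gen, np)
      gens <- sample(params$plants, n_gen, prob = w / sum(w))
      tot <- if (isTRUE(params$fixed_effort)) as.integer(params$mean_samples_per_position)
             else max(1L, stats::rpois(1, params$mean_samples_per_position))
      split <- as.vector(stats::rmultinom(1, tot, rep(1 / n_gen, n_gen)))
      keep <- split > 0
      plan[[i]] <- tibble::tibble(position_id = positions$position_id[i],
                                  host_plant = gens[keep], n_samples = split[keep])
    }
    list(positions = positions, root_plan = dplyr::bind_rows(plan))
  })
}

# Exact Gaussian-process draws over positions: exponential covariance
# exp(-d / range), via Cholesky (cheap for <= a few hundred positions).
gp_fields <- function(xy, range, n_fields) {
  d <- as.matrix(stats::dist(xy))
  cv <- exp(-d / range)
  ch <- chol(cv + diag(1e-8, nrow(cv)))
  t(ch) %*% matrix(stats::rnorm(nrow(cv) * n_fields), nrow(cv), n_fields)
}

#' Simulate the background soil community
#'
#' Per-OTU latent log-abundance fields are Gaussian processes over the
#' sampling positions with exponential covariance (range set per guild);
#' counts are multinomial draws given negative-binomial sequencing depths.
#'
#' @param params A `truth_params` object.
#' @param landscape Output of [generate_landscape()].
#' @param seed Integer seed.
#' @return A list with `table` (soil community matrix, one sample per
#'   position), `latents` (positions x OTUs standardised latent fields for
#'   the root-associated OTUs), `guilds` (tibble), and `otu_ids`.
#' @export
simulate_soil <- function(params, landscape, seed = 1) {
  with_seed(seed, {
    xy <- as.matrix(landscape$positions[, c("x", "y")])
    n_pos <- nrow(xy)
    ge <- params$guild_effects
    otu_guild <- rep(ge$guild, ge$n_otus)
    n_otus <- length(otu_guild)
    otu_ids <- sprintf("OTU_%03d", seq_len(n_otus))
    z <- matrix(0, n_pos, n_otus)
    for (g in seq_len(nrow(ge))) {
      idx <- which(otu_guild == ge$guild[g])
      if (length(idx) > 0)
        z[, idx] <- gp_fields(xy, ge$spatial_range[g], length(idx))
    }
    extra <- params$n_soil_extra_otus
    extra_ids <- if (extra > 0) sprintf("SOIL_%03d", seq_len(extra)) else character(0)
    z_extra <- if (extra > 0) gp_fields(xy, 10, extra) else NULL
    m <- stats::rnorm(n_otus + extra, 0, 1.2)     # lognormal species-abundance spread
    loglam <- cbind(z, z_extra) + matrix(m, n_pos, n_otus + extra, byrow = TRUE)
    p <- exp(loglam); p <- p / rowSums(p)
    depth <- stats::rnbinom(n_pos, mu = params$soil_depth_mean,
                            size = params$soil_depth_size) + 100L
    counts <- t(vapply(seq_len(n_pos),
                       function(i) stats::rmultinom(1, depth[i], p[i, ])[, 1],
                       integer(n_otus + extra)))
    rownames(counts) <- paste0("soil_", landscape$positions$position_id)
    colnames(counts) <- c(otu_ids, extra_ids)
    guilds <- tibble::tibble(otu_id = c(otu_ids, extra_ids),
                             guild = c(otu_guild, rep("Unidentified", extra)))
    colnames(z) <- otu_ids
    rownames(z) <- landscape$positions$position_id
    list(table = validate_community(counts), latents = z,
         guilds = guilds, otu_ids = otu_ids)
  })
}

#' Simulate root-tip communities given a landscape and soil latents
#'
#' Occurrence of OTU \eqn{s} in root sample \eqn{i} is Bernoulli with probit
#' probability
#' \deqn{\Phi(\alpha_s + \beta_{s,host(i)} + c_g z_s(pos_i) + \gamma_g w_s(pos_i)
#'       + \lambda_s' u_i),}
#' where \eqn{z_s} is the OTU's soil latent field, \eqn{w_s} an OTU-specific
#' spatial field, \eqn{u_i \sim N(0, I_r)} a per-sample latent factor, and
#' the scales are set by the OTU's guild archetype. Read counts for present
#' OTUs are multinomial over a lognormal abundance draw, with
#' negative-binomial depths.
#'
#' @param params A `truth_params` object.
#' @param landscape Output of [generate_landscape()].
#' @param soil Output of [simulate_soil()].
#' @param seed Integer seed.
#' @return A list with `table` (root community matrix), `metadata` (root +
#'   soil sample tibble), and `truth` (all generative parameters drawn).
#' @export
simulate_roots <- function(params, landscape, soil, seed = 1) {
  with_seed(seed, {
    ge <- params$guild_effects
    r <- params$n_latent_factors
    otu_ids <- soil$otu_ids
    n_otus <- length(otu_ids)
    if (r > n_otus) stop("latent dimension exceeds the number of OTUs")
    otu_guild <- soil$guilds$guild[match(otu_ids, soil$guilds$otu_id)]
    gidx <- match(otu_guild, ge$guild)
    plan <- landscape$root_plan
    samples <- plan[rep(seq_len(nrow(plan)), plan$n_samples), c("position_id", "host_plant")]
    n <- nrow(samples)
    samples$sample_id <- sprintf("root_%04d", seq_len(n))
    pos_i <- match(samples$position_id, landscape$positions$position_id)

    alpha <- stats::rnorm(n_otus, params$alpha_mean, params$alpha_sd)
    B_plant <- matrix(stats::rnorm(n_otus * length(params$plants)),
                      n_otus, length(params$plants),
                      dimnames = list(otu_ids, params$plants))
    B_plant <- B_plant * ge$plant_effect_sd[gidx]
    xy <- as.matrix(landscape$positions[, c("x", "y")])
    w <- matrix(0, nrow(xy), n_otus)
    for (g in seq_len(nrow(ge))) {
      idx <- which(otu_guild == ge$guild[g])
      if (length(idx) > 0) w[, idx] <- gp_fields(xy, ge$spatial_range[g], length(idx))
    }
    Lambda <- matrix(stats::rnorm(n_otus * r), n_otus, r) * ge$factor_loading_sd[gidx]
    u <- matrix(stats::rnorm(n * r), n, r)

    eta <- matrix(alpha, n, n_otus, byrow = TRUE) +
      t(B_plant[, samples$host_plant, drop = FALSE]) +
      sweep(soil$latents[pos_i, , drop = FALSE], 2, ge$soil_coupling[gidx], `*`) +
      sweep(w[pos_i, , drop = FALSE], 2, ge$spatial_effect_sd[gidx], `*`) +
      u %*% t(Lambda)
    y <- matrix(stats::rbinom(n * n_otus, 1, stats::pnorm(eta)), n, n_otus)

    ab <- exp(matrix(stats::rnorm(n * n_otus, 0, 1), n, n_otus) +
                matrix(stats::rnorm(n_otus, 0, 1), n, n_otus, byrow = TRUE)) * y
    depth <- stats::rnbinom(n, mu = params$root_depth_mean,
                            size = params$root_depth_size) + 50L
    counts <- matrix(0L, n, n_otus, dimnames = list(samples$sample_id, otu_ids))
    for (i in seq_len(n)) {
      if (sum(ab[i, ]) > 0)
        counts[i, ] <- stats::rmultinom(1, depth[i], ab[i, ])[, 1]
    }
    metadata <- dplyr::bind_rows(
      tibble::tibble(sample_id = samples$sample_id, kind = "root",
                     position_id = samples$position_id,
                     x = landscape$positions$x[pos_i],
                     y = landscape$positions$y[pos_i],
                     host_plant = samples$host_plant),
      tibble::tibble(sample_id = rownames(soil$table), kind = "soil",
                     position_id = landscape$positions$position_id,
                     x = landscape$positions$x, y = landscape$positions$y,
                     host_plant = NA_character_))
    truth <- list(alpha = alpha, B_plant = B_plant,
                  soil_coupling = ge$soil_coupling[gidx],
                  spatial_effect_sd = ge$spatial_effect_sd[gidx],
                  spatial_fields = w, Lambda = Lambda, u = u,
                  guild = otu_guild, eta = eta,
                  plant_effect_sd = ge$plant_effect_sd[gidx])
    list(table = validate_community(counts),
         metadata = validate_metadata(metadata), truth = truth)
  })
}

#' Simulate a complete root/soil dataset under a named preset
#'
#' Presets fix the generative conditions:
#' \describe{
#'   \item{`"assembly"`}{100 positions, ~300 root samples, 40 OTUs in three
#'     guild archetypes with strong contrasting effects, 2 latent factors —
#'     the parameter-recovery surface.}
#'   \item{`"null"`}{124 positions, ~1500 root samples, 60 OTUs, every
#'     assembly effect zero and a common intercept — the calibration
#'     surface.}
#' }
#'
#' @param preset `"assembly"` or `"null"`.
#' @param seed Integer seed.
#' @param params Optional `truth_params` overriding the preset.
#' @return A list with `root`, `soil` (community matrices), `metadata`,
#'   `guilds`, and `truth`.
#' @export
simulate_dataset <- function(preset = c("assembly", "null"), seed = 1,
                             params = NULL) {
  preset <- match.arg(preset)
  if (is.null(params)) {
    params <- switch(preset,
      assembly = truth_params(n_positions = 100, arena = 180,
                              mean_samples_per_position = 3,
                              guild_effects = default_guild_effects(),
                              n_latent_factors = 2),
      null = {
        ge <- default_guild_effects()
        ge$n_otus <- c(24L, 21L, 15L)
        ge[, c("plant_effect_sd", "soil_coupling", "spatial_effect_sd",
               "factor_loading_sd")] <- 0
        truth_params(n_positions = 124, mean_samples_per_position = 12,
                     guild_effects = ge, n_latent_factors = 2,
                     alpha_mean = stats::qnorm(0.3), alpha_sd = 0,
                     fixed_effort = TRUE)
      })
  }
  land <- generate_landscape(params, seed = seed)
  soil <- simulate_soil(params, land, seed = seed + 1000L)
  roots <- simulate_roots(params, land, soil, seed = seed + 2000L)
  list(root = roots$table, soil = soil$table, metadata = roots$metadata,
       guilds = soil$guilds, truth = c(roots$truth,
                                       list(soil_latents = soil$latents,
                                            params = params)))
}

#' Simulate a count dataset with known sparse + low-rank precision
#'
#' Latent Gaussian data are drawn with precision \eqn{\Theta = S - L}
#' (\eqn{S} sparse symmetric, \eqn{L} positive semidefinite of rank `rank`)
#' and mapped to counts by a per-OTU negative-binomial quantile transform
#' (Gaussian copula), emulating compositional sequencing counts driven by a
#' sparse direct-association network plus latent environmental confounders.
#'
#' @param p Number of OTUs.
#' @param n Number of samples.
#' @param n_edges Number of true direct associations (off-diagonal support
#'   of `S`).
#' @param rank Rank of the latent (confounder) component `L`.
#' @param seed Integer seed.
#' @param edge_strength Magnitude of off-diagonal entries of `S`.
#' @param confounder_strength Leading eigenvalue scale of `L`.
#' @return A list with `counts`, `S_true`, `L_true`, `Theta` and the edge
#'   list `edges_true`.
#' @export
generate_network_dataset <- function(p = 50, n = 500, n_edges = 40, rank = 3,
                                     seed = 1, edge_strength = 0.3,
                                     confounder_strength = 0.85) {
  with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    stopifnot(n_edges <= nrow(pairs))
    sel <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    S <- diag(p)
    for (e in seq_len(nrow(sel))) {
      v <- edge_strength * sample(c(-1, 1), 1)
      S[sel[e, 1], sel[e, 2]] <- S[sel[e, 2], sel[e, 1]] <- v
    }
    L <- matrix(0, p, p)
    if (rank > 0) {
      V <- qr.Q(qr(matrix(stats::rnorm(p * rank), p, rank)))
      L <- V %*% diag(confounder_strength * seq(1, 0.6, length.out = rank),
                      rank) %*% t(V)
    }
    emin <- min(eigen(S - L, symmetric = TRUE, only.values = TRUE)$values)
    if (emin < 0.1) S <- S + diag(0.1 - emin, p)
    Theta <- S - L
    Sigma <- solve(Theta)
    z <- matrix(stats::rnorm(n * p), n, p) %*% chol(Sigma)
    uq <- stats::pnorm(sweep(z, 2, sqrt(diag(Sigma)), `/`))
    mu <- exp(stats::rnorm(p, log(50), 1))
    counts <- vapply(seq_len(p),
                     function(j) stats::qnbinom(uq[, j], size = 2, mu = mu[j]),
                     numeric(n))
    counts <- matrix(as.integer(counts), n, p,
                     dimnames = list(sprintf("s%04d", seq_len(n)),
                                     sprintf("OTU_%03d", seq_len(p))))
    list(counts = validate_community(counts), S_true = S, L_true = L,
         Theta = Theta,
         edges_true = sel[order(sel[, 1], sel[, 2]), , drop = FALSE])
  })
}
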