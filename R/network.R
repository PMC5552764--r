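#' Projection specification
#'
#' Attributes of one synaptic pathway between populations: each ordered
#' (pre, post) cell pair is connected independently with probability
#' `p_conn`; a realized connection delivers weight `w_syn` (nA) after delay
#' `d_conn` (ms) with the pathway's sign.
#'
#' @param pre,post population roles (`"TCR"`, `"IN"`, `"TRN"`, `"RET"`).
#' @param p_conn connection probability in (0, 1].
#' @param w_syn synaptic weight, nA (> 0).
#' @param d_conn transmission delay, ms (must be >= the simulation step).
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @return Object of class `projection_spec` (a one-row data frame).
#' @export
projection_spec <- function(pre, post, p_conn, w_syn, d_conn, sign) {
  if (!is.numeric(p_conn) || p_conn <= 0 || p_conn > 1)
    stop("projection_spec: p_conn must lie in (0, 1]")
  if (w_syn <= 0) stop("projection_spec: w_syn must be > 0")
  if (d_conn <= 0) stop("projection_spec: d_conn must be > 0")
  sign <- match.arg(sign, c("excitatory", "inhibitory"))
  structure(data.frame(pre = pre, post = post, p_conn = p_conn,
                       w_syn = w_syn, d_conn = d_conn, sign = sign,
                       stringsAsFactors = FALSE),
            class = c("projection_spec", "data.frame"))
}

#' Network configuration
#'
#' Assembles the model configuration from the packaged defaults: population
#' sizes (TCR 80, IN 20, TRN 40 — the 8:2:4 proportion over 140 neurons —
#' plus 144 retinal source channels), Izhikevich presets, the seven
#' anatomically derived projections, synapse kinetics and analysis settings.
#'
#' @param variant `"base"` (feed-forward inhibition dominant) or
#'   `"in_suppressed"` (IN->TCR weakened to p=0.07, w=1 nA; TRN->TCR raised
#'   to p=0.309).
#' @param overrides optional named list merged over the defaults (same shape
#'   as the defaults YAML), validated after merging.
#' @return Object of class `lgn_config`.
#' @examples
#' cfg <- lgn_config()
#' subset(cfg$projections, pre == "RET")
#' @export
lgn_config <- function(variant = c("base", "in_suppressed"),
                       overrides = NULL) {
  variant <- match.arg(variant)
  def <- lgn_defaults()
  if (!is.null(overrides)) def <- merge_config(def, overrides)
  proj <- do.call(rbind, lapply(def$projections, function(p)
    data.frame(pre = p$pre, post = p$post, p_conn = p$p_conn,
               w_syn = p$w_syn, d_conn = p$d_conn, sign = p$sign,
               stringsAsFactors = FALSE)))
  cfg <- structure(list(
    populations = def$populations,
    projections = proj,
    kinetics = syn_kinetics(def$kinetics$tau_e, def$kinetics$tau_i),
    variant = "base",
    node_count = 1L,
    simulation = def$simulation,
    analysis = def$analysis,
    dvs = def$dvs,
    variant_defs = def$variants), class = "lgn_config")
  validate_config(cfg)
  if (variant == "in_suppressed") cfg <- apply_in_suppression(cfg)
  cfg
}

merge_config <- function(def, overrides) {
  stopifnot(is.list(overrides))
  known <- names(def)
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(overrides$projections)) {
    # projection overrides are matched on (pre, post) and merged field-wise
    for (ov in overrides$projections) {
      if (is.null(ov$pre) || is.null(ov$post))
        stop("projection override needs 'pre' and 'post'")
      hit <- FALSE
      for (i in seq_along(def$projections)) {
        p <- def$projections[[i]]
        if (p$pre == ov$pre && p$post == ov$post) {
          def$projections[[i]] <- modifyList(p, ov)
          hit <- TRUE
        }
      }
      if (!hit) stop(sprintf("no such pathway to override: %s->%s",
                             ov$pre, ov$post))
    }
    overrides$projections <- NULL
  }
  modifyList(def, overrides)
}

validate_config <- function(cfg) {
  pops <- cfg$populations
  for (nm in c("TCR", "IN", "TRN", "RET")) {
    if (is.null(pops[[nm]])) stop("configuration: missing population ", nm)
    if (pops[[nm]]$size < 1) stop("configuration: populations.", nm,
                                  ".size must be >= 1")
  }
  allowed <- c("TCR>TRN", "IN>TCR", "IN>IN", "TRN>TCR", "TRN>TRN",
               "RET>TCR", "RET>IN")
  keys <- paste(cfg$projections$pre, cfg$projections$post, sep = ">")
  bad <- setdiff(keys, allowed)
  if (length(bad))
    stop("configuration: unknown pathway(s): projections ",
         paste(bad, collapse = ", "))
  for (i in seq_len(nrow(cfg$projections))) {
    p <- cfg$projections[i, ]
    if (p$p_conn <= 0 || p$p_conn > 1)
      stop(sprintf("configuration: projections[%s->%s].p_conn = %g outside (0, 1]",
                   p$pre, p$post, p$p_conn))
    if (p$w_syn <= 0)
      stop(sprintf("configuration: projections[%s->%s].w_syn must be > 0",
                   p$pre, p$post))
    if (p$d_conn < cfg$simulation$dt)
      stop(sprintf("configuration: projections[%s->%s].d_conn shorter than dt",
                   p$pre, p$post))
  }
  invisible(cfg)
}

#' Suppress the feed-forward inhibition
#'
#' Produces the variant in which the interneurons' feed-forward inhibitory
#' role is diminished and the reticular feedback inhibition is dominant:
#' IN->TCR is set to p_conn = 0.07, w_syn = 1 nA and TRN->TCR to
#' p_conn = 0.309.  All other attributes (including every delay) are left
#' untouched.  Applying the transform twice is a no-op with a warning.
#'
#' @param cfg an [lgn_config()].
#' @return The modified configuration, `variant = "in_suppressed"`.
#' @export
apply_in_suppression <- function(cfg) {
  stopifnot(inherits(cfg, "lgn_config"))
  if (identical(cfg$variant, "in_suppressed")) {
    warning("apply_in_suppression: configuration already in_suppressed; unchanged")
    return(cfg)
  }
  for (ov in cfg$variant_defs$in_suppressed) {
    i <- which(cfg$projections$pre == ov$pre & cfg$projections$post == ov$post)
    if (!is.null(ov$p_conn)) cfg$projections$p_conn[i] <- ov$p_conn
    if (!is.null(ov$w_syn)) cfg$projections$w_syn[i] <- ov$w_syn
  }
  cfg$variant <- "in_suppressed"
  cfg
}

#' Realize one probabilistic projection
#'
#' Draws the edge list of a pathway: every ordered (pre, post) pair is
#' included independently with probability `p_conn`.  When the pathway is a
#' self-projection (`self = TRUE`) autapses (pre == post) are excluded.
#' The draw is deterministic given `seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param spec a [projection_spec()] (or one row of a projection table).
#' @param n_pre,n_post population sizes.
#' @param seed integer seed.
#' @param self logical: is this a within-population projection?
#' @param dt time-step used to convert the delay to steps, ms.
#' @return Data frame with columns `pre`, `post` (1-based indices), `weight`
#'   (nA), `delay_steps`, `sign`.
#' @examples
#' realize_projection(projection_spec("RET", "TCR", 0.071, 5, 10, "excitatory"),
#'                    n_pre = 144, n_post = 80, seed = 1)
#' @export
realize_projection <- function(spec, n_pre, n_post, seed, self = FALSE,
                               dt = 0.1) {
  if (spec$p_conn <= 0 || spec$p_conn > 1)
    stop("realize_projection: p_conn outside (0, 1]")
  stopifnot(n_pre >= 1, n_post >= 1)
  with_local_seed(seed,
    draw_projection(spec, n_pre, n_post, self, dt))
}

# RNG-consuming part, callable inside an established seed context
draw_projection <- function(spec, n_pre, n_post, self, dt) {
  keep <- runif(n_pre * n_post) < spec$p_conn
  pre <- rep(seq_len(n_pre), times = n_post)
  post <- rep(seq_len(n_post), each = n_pre)
  if (self) keep <- keep & (pre != post)
  n <- sum(keep)
  data.frame(pre = pre[keep], post = post[keep],
             weight = rep(spec$w_syn, n),
             delay_steps = rep(max(1L, as.integer(round(spec$d_conn / dt))), n),
             sign = rep(spec$sign, n), stringsAsFactors = FALSE)
}

#' Build the single-node LGN network
#'
#' Instantiates the 140-neuron model: TCR (80), IN (20), TRN (40) with the
#' tonic-firing presets and `I_dc = 0`, the 144 retinal source channels, and
#' the configured pathways (TCR->TRN excitatory; IN->TCR, IN->IN, TRN->TCR,
#' TRN->TRN inhibitory; RET->TCR, RET->IN excitatory).  There is no TCR->IN
#' pathway.  Connectivity is probabilistic and realized per trial; the
#' returned object carries the specifications only.
#'
#' @param config an [lgn_config()].
#' @return Object of class `lgn_network` with elements `pops` (population
#'   table with global index offsets), `params` (per population),
#'   `projections`, `n_neurons`, `n_sources`, `kinetics`, `variant`,
#'   `node_count`.
#' @examples
#' net <- build_lgn(lgn_config())
#' net$n_neurons
#' @export
build_lgn <- function(config = lgn_config()) {
  stopifnot(inherits(config, "lgn_config"))
  validate_config(config)
  sizes <- vapply(config$populations[c("TCR", "IN", "TRN")],
                  function(p) as.integer(p$size), 1L)
  pops <- data.frame(name = names(sizes), role = names(sizes), node = 1L,
                     size = unname(sizes),
                     offset = cumsum(c(0L, unname(sizes)))[seq_along(sizes)],
                     stringsAsFactors = FALSE)
  presets <- izh_presets()
  params <- presets[pops$role]
  names(params) <- pops$name
  proj <- config$projections
  proj$pre_name <- proj$pre
  proj$post_name <- proj$post
  structure(list(pops = pops, params = params, projections = proj,
                 n_neurons = sum(sizes),
                 n_sources = as.integer(config$populations$RET$size),
                 kinetics = config$kinetics,
                 variant = config$variant,
                 node_count = 1L,
                 config = config),
            class = "lgn_network")
}

#' Build the multi-node scaled architecture
#'
#' Replicates the basic network `n_nodes` times (420 neurons for three
#' nodes) and wires every ordered pair of distinct nodes i != j with
#' TCR_i -> TRN_j (excitatory, TCR->TRN attributes), TRN_i -> TCR_j
#' (inhibitory, TRN->TCR attributes) and TRN_i -> TRN_j (inhibitory,
#' TRN->TRN attributes).  Interneurons are local: no inter-node projection
#' touches an IN population.  Inter-node attributes equal the corresponding
#' intra-node ones (the nodes are treated as equidistant), so a variant
#' applied to the configuration propagates to the inter-node pathways.  All
#' nodes share the same 144 retinal source channels (wired independently to
#' each node).
#'
#' @param config an [lgn_config()].
#' @param n_nodes number of nodes (>= 2).
#' @return An `lgn_network` with `node_count = n_nodes`.
#' @examples
#' net3 <- build_multi_node(lgn_config(), n_nodes = 3)
#' net3$n_neurons
#' @export
build_multi_node <- function(config = lgn_config(), n_nodes = 3L) {
  if (n_nodes < 2) stop("build_multi_node: n_nodes must be >= 2")
  base <- build_lgn(config)
  n_nodes <- as.integer(n_nodes)
  pops <- do.call(rbind, lapply(seq_len(n_nodes), function(k) {
    p <- base$pops
    p$name <- paste0(p$role, "@", k)
    p$node <- k
    p
  }))
  pops$offset <- cumsum(c(0L, pops$size))[seq_len(nrow(pops))]
  params <- rep(base$params, n_nodes)
  names(params) <- pops$name

  intra <- do.call(rbind, lapply(seq_len(n_nodes), function(k) {
    pr <- base$projections
    pr$pre_name <- ifelse(pr$pre == "RET", "RET", paste0(pr$pre, "@", k))
    pr$post_name <- paste0(pr$post, "@", k)
    pr
  }))
  attr_of <- function(pre, post)
    base$projections[base$projections$pre == pre &
                     base$projections$post == post, ]
  pairs <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
  pairs <- pairs[pairs$i != pairs$j, ]
  inter <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    rbind(
      within(attr_of("TCR", "TRN"), {
        pre_name <- paste0("TCR@", i); post_name <- paste0("TRN@", j) }),
      within(attr_of("TRN", "TCR"), {
        pre_name <- paste0("TRN@", i); post_name <- paste0("TCR@", j) }),
      within(attr_of("TRN", "TRN"), {
        pre_name <- paste0("TRN@", i); post_name <- paste0("TRN@", j) }))
  }))
  structure(list(pops = pops, params = params,
                 projections = rbind(intra, inter),
                 n_neurons = sum(pops$size),
                 n_sources = base$n_sources,
                 kinetics = base$kinetics,
                 variant = base$variant,
                 node_count = n_nodes,
                 config = config),
            class = "lgn_network")
}

#' @export
print.lgn_network <- function(x, ...) {
  cat(sprintf("LGN network: %d neurons in %d population(s), %d node(s), variant '%s'\n",
              x$n_neurons, nrow(x$pops), x$node_count, x$variant))
  cat(sprintf("  %d retinal source channels, %d projection pathways\n",
              x$n_sources, nrow(x$projections)))
  invisible(x)
}

#' Realize all projections of a network
#'
#' Draws every pathway's edge list (Bernoulli per ordered pair, autapses
#' excluded within a population) under a single seed, in the fixed order of
#' the projection table, and maps endpoints to global neuron indices.
#' Retinal pathways keep 1-based source-channel indices and are flagged
#' `from_source`.
#'
#' @param network an `lgn_network`.
#' @param seed integer seed (deterministic, bit-exact edge lists).
#' @param dt time-step, ms.
#' @return Data frame of edges: `pre`, `post` (global 1-based), `weight`,
#'   `delay_steps`, `sign`, `from_source`, `pathway`.
#' @export
realize_network <- function(network, seed, dt = 0.1) {
  stopifnot(inherits(network, "lgn_network"))
  offs <- setNames(network$pops$offset, network$pops$name)
  sizes <- setNames(network$pops$size, network$pops$name)
  with_local_seed(seed, {
    out <- lapply(seq_len(nrow(network$projections)), function(i) {
      pr <- network$projections[i, ]
      from_src <- pr$pre == "RET"
      n_pre <- if (from_src) network$n_sources else sizes[[pr$pre_name]]
      e <- draw_projection(pr, n_pre, sizes[[pr$post_name]],
                           self = !from_src && pr$pre_name == pr$post_name,
                           dt = dt)
      if (!from_src) e$pre <- e$pre + offs[[pr$pre_name]]
      e$post <- e$post + offs[[pr$post_name]]
      e$from_source <- from_src
      e$pathway <- paste0(pr$pre_name, "->", pr$post_name)
      e
    })
    do.call(rbind, out)
  })
}

#' Export a realized edge list as tab-separated text
#'
#' @param edges data frame from [realize_network()].
#' @param path output file.
#' @param dt time-step used to convert `delay_steps` back to ms.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path, dt = 0.1) {
  out <- data.frame(pre = edges$pre, post = edges$post,
                    weight = edges$weight,
                    delay_ms = edges$delay_steps * dt,
                    sign = edges$sign)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
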