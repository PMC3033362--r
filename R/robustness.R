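#' Specification of simulated reconstruction errors
#'
#' Reconstruction errors and animal-to-animal variability are emulated by
#' relocating individual synaptic contacts: each unit of multiplicity is
#' independently moved, with its type's probability, to a uniformly random
#' pair of neurons (ordered for chemical contacts, unordered for gap
#' junctions, never a self-pair). Total contact counts per type are
#' conserved exactly.
#'
#' @param p_gap,p_chem per-contact relocation probabilities in [0, 1].
#' @param n_networks ensemble size.
#' @param seed integer seed; edit draws are indexed deterministically.
#' @return an \code{edit_spec} list.
#' @export
edit_spec <- function(p_gap = 0.05, p_chem = 0.05, n_networks = 20,
                      seed = 1L) {
  if (p_gap < 0 || p_gap > 1 || p_chem < 0 || p_chem > 1)
    stop("relocation probabilities must lie in [0, 1]")
  if (n_networks < 1) stop("n_networks must be >= 1")
  structure(list(p_gap = p_gap, p_chem = p_chem,
                 n_networks = as.integer(n_networks), seed = as.integer(seed)),
            class = "edit_spec")
}

# expand records of one type into unit contacts, relocate, re-aggregate
relocate_contacts <- function(rec, p, names, ordered) {
  if (!nrow(rec) || p == 0) return(rec)
  n <- length(names)
  idx <- setNames(seq_along(names), names)
  reps <- rep.int(seq_len(nrow(rec)), rec$contacts)
  pre <- idx[rec$pre][reps]
  post <- idx[rec$post][reps]
  # polyadic flags distributed over the unit contacts of each record
  poly <- unlist(lapply(seq_len(nrow(rec)), function(r)
    c(rep(TRUE, rec$polyadic[r]), rep(FALSE, rec$contacts[r] - rec$polyadic[r]))),
    use.names = FALSE)
  mv <- runif(length(pre)) < p
  nm <- sum(mv)
  if (nm) {
    a <- sample.int(n, nm, replace = TRUE)
    b <- sample.int(n - 1, nm, replace = TRUE)
    b <- ifelse(b >= a, b + 1L, b)      # uniform over pairs excluding self
    if (!ordered) {                     # unordered: canonical i < j
      lo <- pmin(a, b); hi <- pmax(a, b)
      a <- lo; b <- hi
    }
    pre[mv] <- a
    post[mv] <- b
  }
  if (!ordered) {
    lo <- pmin(pre, post); hi <- pmax(pre, post)
    pre <- lo; post <- hi
  }
  key <- paste(pre, post)
  agg_c <- tapply(rep(1L, length(pre)), key, sum)
  agg_p <- tapply(as.integer(poly), key, sum)
  ij <- do.call(rbind, lapply(strsplit(names(agg_c), " "), as.integer))
  data.frame(pre = names[ij[, 1]], post = names[ij[, 2]],
             type = rec$type[1], contacts = as.numeric(agg_c),
             polyadic = as.numeric(agg_p), stringsAsFactors = FALSE)
}

#' Apply one random edit to a wiring diagram
#'
#' Deterministic given \code{(spec$seed, draw_index)}. Gap-junction
#' relocations act on unordered pairs, so the edited gap network stays
#' symmetric (paired records are regenerated in both directions);
#' chemical relocations act on ordered pairs. Relocated contacts may land
#' on already-connected pairs, stacking multiplicity.
#'
#' @param diagram a \code{wiring_diagram}.
#' @param spec an \code{\link{edit_spec}}.
#' @param draw_index which ensemble member to generate (1-based).
#' @return the edited \code{wiring_diagram}.
#' @export
edit_diagram <- function(diagram, spec, draw_index = 1) {
  stopifnot(inherits(diagram, "wiring_diagram"), inherits(spec, "edit_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((spec$seed + 1000003 * as.integer(draw_index)) %% 2147483647)
  nm <- diagram$neurons$name
  r <- diagram$records
  chem <- r[r$type == "chem", , drop = FALSE]
  gap <- r[r$type == "gap", , drop = FALSE]
  nmj <- r[r$type == "nmj", , drop = FALSE]
  chem2 <- relocate_contacts(chem, spec$p_chem, nm, ordered = TRUE)
  # gap contacts are counted once per unordered pair (records come in
  # mirrored pairs); relocate the i<j representatives, then re-mirror
  if (nrow(gap)) {
    rep1 <- gap[gap$pre < gap$post, , drop = FALSE]
    g2 <- relocate_contacts(rep1, spec$p_gap, nm, ordered = FALSE)
    gap2 <- rbind(g2, within(g2, {tmp <- pre; pre <- post; post <- tmp;
                                  rm(tmp)})[, names(g2)])
  } else gap2 <- gap
  wiring_diagram(diagram$neurons, rbind(chem2, gap2, nmj))
}

#' Global network properties over an ensemble of edited wiring diagrams
#'
#' Recomputes the requested global metrics on \code{spec$n_networks}
#' independently edited copies of the diagram and summarizes their spread
#' around the unedited value. The \code{"spectrum"} metric reports, for
#' each unedited eigenvalue of the combined weighted dynamics matrix, the
#' displacement to the nearest edited eigenvalue.
#'
#' @param diagram a \code{wiring_diagram}.
#' @param spec an \code{\link{edit_spec}}.
#' @param metrics subset of \code{c("giant_component", "L", "C", "S",
#'   "degree_extremes", "spectrum")}.
#' @param network which network the scalar metrics are computed on:
#'   \code{"gap"}, \code{"chemical"} or \code{"combined"} (binary).
#' @param null_spec ensemble used by the \code{"S"} metric.
#' @return list with per-metric results: \code{unedited}, \code{values}
#'   (per edit), \code{mean}, \code{sd}; for \code{"spectrum"} the
#'   per-eigenvalue nearest-neighbour displacements.
#' @export
robustness_ensemble <- function(diagram, spec,
                                metrics = c("giant_component", "L", "C"),
                                network = c("gap", "chemical", "combined"),
                                null_spec = null_ensemble_spec(n_samples = 20)) {
  network <- match.arg(network)
  known <- c("giant_component", "L", "C", "S", "degree_extremes", "spectrum")
  bad <- setdiff(metrics, known)
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))

  get_net <- function(d) {
    switch(network,
      gap = build_network(d, "gap", check_consistency = FALSE),
      chemical = build_network(d, "chemical", check_consistency = FALSE),
      combined = {
        al <- align_networks(build_network(d, "gap", check_consistency = FALSE),
                             build_network(d, "chemical",
                                           check_consistency = FALSE))
        combine_networks(al$a, al$b, "binary")
      })
  }
  get_M <- function(d) {
    al <- align_networks(build_network(d, "gap", check_consistency = FALSE),
                         build_network(d, "chemical", check_consistency = FALSE))
    gc_names <- giant_component(combine_networks(al$a, al$b, "binary"))$names
    sub <- function(net) adjacency_network(
      net$weights[gc_names, gc_names, drop = FALSE], gc_names,
      net$directed, net$quantitation)
    dynamics_matrix(sub(al$a), sub(al$b),
                    signs = neuron_signs(diagram))
  }
  scalar_metrics <- function(d) {
    out <- c()
    net <- get_net(d)
    if ("giant_component" %in% metrics) {
      part <- connected_components(if (net$directed) net else net,
                                   if (net$directed) "strong" else "undirected")
      out <- c(out, giant_component = length(part$components[[1]]))
    }
    if (any(c("L", "C") %in% metrics)) {
      gcn <- giant_component(net)
      if ("L" %in% metrics) out <- c(out, L = path_stats(gcn)$L)
      if ("C" %in% metrics)
        out <- c(out, C = clustering(gcn, if (net$directed) "out"
                                     else "undirected")$C)
    }
    if ("S" %in% metrics)
      out <- c(out, S = small_world_ness(net, null_spec)$S)
    if ("degree_extremes" %in% metrics) {
      B <- net$weights > 0
      out <- c(out, max_in_degree = max(colSums(B)),
               max_out_degree = max(rowSums(B)))
    }
    out
  }
  base <- scalar_metrics(diagram)
  vals <- matrix(NA_real_, spec$n_networks, length(base),
                 dimnames = list(NULL, names(base)))
  spectra <- NULL
  base_ev <- NULL
  if ("spectrum" %in% metrics) {
    base_ev <- eigen(get_M(diagram), only.values = TRUE)$values
    spectra <- vector("list", spec$n_networks)
  }
  for (i in seq_len(spec$n_networks)) {
    d <- edit_diagram(diagram, spec, i)
    if (length(base)) vals[i, ] <- scalar_metrics(d)
    if (!is.null(spectra))
      spectra[[i]] <- eigen(get_M(d), only.values = TRUE)$values
  }
  out <- list(network = network, spec = spec)
  for (m in colnames(vals)) {
    out[[m]] <- list(unedited = unname(base[m]), values = unname(vals[, m]),
                     mean = mean(vals[, m]), sd = sd(vals[, m]))
  }
  if (!is.null(spectra)) {
    disp <- vapply(base_ev, function(ev)
      min(vapply(spectra, function(s) min(Mod(s - ev)), numeric(1))),
      numeric(1))
    nearest_per_edit <- lapply(spectra, function(s)
      vapply(base_ev, function(ev) min(Mod(s - ev)), numeric(1)))
    out$spectrum <- list(unedited = base_ev, edited = spectra,
                         displacement = disp,
                         displacement_per_edit = nearest_per_edit)
  }
  out
}
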