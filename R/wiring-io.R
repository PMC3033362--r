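#' @useDynLib wirenet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test optim optimize quantile rbinom runif sd
#'   setNames uniroot rgeom
#' @importFrom utils read.csv write.csv combn head
NULL

NEURON_CATEGORIES <- c("sensory", "interneuron", "motor")
SYN_TYPES <- c("chem", "gap", "nmj")

#' Construct a wiring diagram from neuron and synapse tables
#'
#' A wiring diagram is the single source of truth for all analyses: a table
#' of neurons (name, category, GABAergic flag, body side, anatomical class)
#' plus a list of synapse records (presynaptic neuron, postsynaptic neuron,
#' synapse type, number of synaptic contacts, and how many of those contacts
#' are polyadic, i.e. shared with an adjacent candidate postsynaptic
#' process).
#'
#' Self-records (\code{pre == post}) are rejected: neuron-to-neuron networks
#' here have zero diagonal by construction. Neuromuscular (\code{nmj})
#' records are kept in the record table but never enter neuron-to-neuron
#' adjacency matrices.
#'
#' @param neurons data.frame with columns \code{name}, \code{category}
#'   (\code{"sensory"}, \code{"interneuron"}, \code{"motor"} or codes
#'   \code{"S"}, \code{"I"}, \code{"M"}), \code{gabaergic} (logical or 0/1),
#'   \code{side} (\code{"L"}, \code{"R"} or \code{"none"}), \code{class}.
#' @param records data.frame with columns \code{pre}, \code{post},
#'   \code{type} (\code{"chem"}, \code{"gap"}, \code{"nmj"}),
#'   \code{contacts}, \code{polyadic}.
#' @return An object of class \code{wiring_diagram}.
#' @export
wiring_diagram <- function(neurons, records) {
  neurons <- as.data.frame(neurons, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req_n <- c("name", "category", "gabaergic", "side", "class")
  req_r <- c("pre", "post", "type", "contacts", "polyadic")
  if (!all(req_n %in% names(neurons)))
    stop("neuron table missing column(s): ",
         paste(setdiff(req_n, names(neurons)), collapse = ", "))
  if (!all(req_r %in% names(records)))
    stop("synapse table missing column(s): ",
         paste(setdiff(req_r, names(records)), collapse = ", "))
  neurons$name <- as.character(neurons$name)
  cat_map <- c(S = "sensory", I = "interneuron", M = "motor",
               sensory = "sensory", interneuron = "interneuron",
               motor = "motor")
  neurons$category <- unname(cat_map[as.character(neurons$category)])
  if (anyNA(neurons$category))
    stop("neuron category must be one of S/I/M (or spelled out)")
  g <- neurons$gabaergic
  if (is.character(g)) g <- trimws(g) %in% c("1", "TRUE", "true", "T")
  neurons$gabaergic <- as.logical(g)
  if (anyNA(neurons$gabaergic)) stop("gabaergic must be 0/1 or logical")
  neurons$side <- as.character(neurons$side)
  neurons$class <- as.character(neurons$class)
  if (anyDuplicated(neurons$name))
    stop("duplicate neuron name(s): ",
         paste(unique(neurons$name[duplicated(neurons$name)]), collapse = ", "))

  if (nrow(records)) {
    records$pre <- as.character(records$pre)
    records$post <- as.character(records$post)
    records$type <- as.character(records$type)
    records$contacts <- as.numeric(records$contacts)
    records$polyadic <- as.numeric(records$polyadic)
    if (!all(records$type %in% SYN_TYPES))
      stop("synapse type must be one of: ", paste(SYN_TYPES, collapse = ", "))
    bad <- which(records$pre == records$post)
    if (length(bad))
      stop("self-record (pre == post) at synapse row(s): ",
           paste(head(bad, 10), collapse = ", "))
    if (any(records$contacts < 1) || any(records$contacts != round(records$contacts)))
      stop("contacts must be positive integers")
    if (any(records$polyadic < 0) || any(records$polyadic > records$contacts))
      stop("polyadic contact counts must lie in [0, contacts]")
    # nmj posts are muscle targets, not neurons; only neuron ends must resolve
    ends <- unique(c(records$pre, records$post[records$type != "nmj"]))
    unknown <- setdiff(ends, neurons$name)
    if (length(unknown))
      stop("synapse record(s) reference undeclared neuron(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(neurons = neurons, records = records),
            class = "wiring_diagram")
}

#' @export
print.wiring_diagram <- function(x, ...) {
  r <- x$records
  cat("wiring_diagram:", nrow(x$neurons), "neurons,", nrow(r), "records\n")
  if (nrow(r))
    cat("  chem:", sum(r$type == "chem"), " gap:", sum(r$type == "gap"),
        " nmj:", sum(r$type == "nmj"), "\n")
  invisible(x)
}

#' Load a wiring diagram from the canonical CSV pair
#'
#' The neuron table has header \code{name,category,gabaergic,side,class}
#' with category codes S/I/M and gabaergic 0/1; the synapse table has header
#' \code{pre,post,type,contacts,polyadic} with type in chem/gap/nmj.
#'
#' @param neuron_path,synapse_path paths to the two CSV files.
#' @return a \code{wiring_diagram}.
#' @export
load_wiring_diagram <- function(neuron_path, synapse_path) {
  for (p in c(neuron_path, synapse_path))
    if (!file.exists(p)) stop("file not found: ", p)
  neurons <- read.csv(neuron_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  records <- read.csv(synapse_path, stringsAsFactors = FALSE)
  wiring_diagram(neurons, records)
}

#' Write a wiring diagram to the canonical CSV pair
#'
#' Inverse of \code{\link{load_wiring_diagram}}: a load/write/load round
#' trip is the identity.
#'
#' @param diagram a \code{wiring_diagram}.
#' @param neuron_path,synapse_path output CSV paths.
#' @export
write_wiring_diagram <- function(diagram, neuron_path, synapse_path) {
  stopifnot(inherits(diagram, "wiring_diagram"))
  nt <- diagram$neurons
  nt$category <- c(sensory = "S", interneuron = "I", motor = "M")[nt$category]
  nt$gabaergic <- as.integer(nt$gabaergic)
  write.csv(nt[, c("name", "category", "gabaergic", "side", "class")],
            neuron_path, row.names = FALSE, quote = FALSE)
  rt <- diagram$records
  write.csv(rt[, c("pre", "post", "type", "contacts", "polyadic")],
            synapse_path, row.names = FALSE, quote = FALSE)
  invisible(c(neuron_path, synapse_path))
}

#' Check self-consistency of a wiring diagram
#'
#' Reconstructed connectivity data must be internally consistent: every gap
#' junction between i and j must be recorded from both sides, and no ordered
#' (pre, post, type) triple may appear twice. Violations are returned as
#' data, not raised as errors.
#'
#' @param diagram a \code{wiring_diagram}.
#' @return data.frame with columns \code{kind} (\code{"unpaired gap"},
#'   \code{"gap count mismatch"}, \code{"duplicate"}), \code{pre},
#'   \code{post}, \code{type}, \code{detail}. Zero rows iff consistent.
#' @export
validate_consistency <- function(diagram) {
  stopifnot(inherits(diagram, "wiring_diagram"))
  r <- diagram$records
  out <- data.frame(kind = character(), pre = character(), post = character(),
                    type = character(), detail = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(r)) return(out)
  key <- paste(r$pre, r$post, r$type, sep = "\r")
  dup <- unique(key[duplicated(key)])
  for (k in dup) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1]]
    out <- rbind(out, data.frame(
      kind = "duplicate", pre = p[1], post = p[2], type = p[3],
      detail = sprintf("%d records for the same ordered pair", sum(key == k)),
      stringsAsFactors = FALSE))
  }
  g <- r[r$type == "gap", , drop = FALSE]
  if (nrow(g)) {
    fw <- paste(g$pre, g$post, sep = "\r")
    bw <- paste(g$post, g$pre, sep = "\r")
    miss <- which(!(bw %in% fw))
    for (i in miss)
      out <- rbind(out, data.frame(
        kind = "unpaired gap", pre = g$pre[i], post = g$post[i], type = "gap",
        detail = sprintf("no paired record (%s,%s)", g$post[i], g$pre[i]),
        stringsAsFactors = FALSE))
    have <- which(bw %in% fw & g$pre < g$post)  # report each pair once
    for (i in have) {
      j <- match(bw[i], fw)
      if (g$contacts[i] != g$contacts[j])
        out <- rbind(out, data.frame(
          kind = "gap count mismatch", pre = g$pre[i], post = g$post[i],
          type = "gap",
          detail = sprintf("counts %g vs %g", g$contacts[i], g$contacts[j]),
          stringsAsFactors = FALSE))
    }
  }
  out
}

#' Construct an adjacency-network object
#'
#' Thin container for a weighted adjacency matrix with a neuron-name index.
#' For an undirected network the matrix must be symmetric; the diagonal is
#' always zero.
#'
#' @param weights square non-negative numeric matrix, rows = presynaptic.
#' @param names neuron names (defaults to rownames).
#' @param directed logical.
#' @param quantitation \code{"full"} (each contact counts 1) or
#'   \code{"polyad_split"} (each polyadic contact counts a fraction).
#' @return object of class \code{adjacency_network}.
#' @export
adjacency_network <- function(weights, names = rownames(weights),
                              directed = TRUE, quantitation = "full") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (is.null(names)) names <- paste0("V", seq_len(nrow(weights)))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  if (!directed && nrow(weights) &&
      max(abs(weights - t(weights))) > 0)
    stop("undirected network requires a symmetric matrix")
  dimnames(weights) <- list(names, names)
  structure(list(names = as.character(names), weights = weights,
                 directed = directed, quantitation = quantitation),
            class = "adjacency_network")
}

#' @export
print.adjacency_network <- function(x, ...) {
  m <- if (x$directed) sum(x$weights > 0) else sum(x$weights > 0) / 2
  cat(sprintf("adjacency_network: %d neurons, %g %s connections (%s)\n",
              length(x$names), m, if (x$directed) "directed" else "undirected",
              x$quantitation))
  invisible(x)
}

n_nodes <- function(net) length(net$names)

binarize <- function(net) {
  w <- (net$weights > 0) * 1
  adjacency_network(w, net$names, net$directed, net$quantitation)
}

is_binary <- function(net) all(net$weights %in% c(0, 1))

#' Build an adjacency network from a wiring diagram
#'
#' Chemical synapses give a directed matrix with \code{A[i, j]} = number of
#' synaptic contacts from i to j. Gap junctions give a symmetric matrix;
#' paired (i,j)/(j,i) records are merged (taking the larger stated count if
#' they disagree), never double-counted. Under \code{polyad_split}
#' quantitation each polyadic contact contributes \code{polyad_weight}
#' instead of 1, reflecting the counting ambiguity of send_joint synapses.
#'
#' @param diagram a consistent \code{wiring_diagram}.
#' @param syn_type \code{"chemical"} or \code{"gap"}.
#' @param quantitation \code{"full"} or \code{"polyad_split"}.
#' @param polyad_weight weight of one polyadic contact under
#'   \code{polyad_split} (default 1/2: a dyad shared between two candidates).
#' @param drop_isolated drop neurons with no synapse of the requested type
#'   (default TRUE, mirroring the exclusion of non-synapsing neurons).
#' @param check_consistency refuse on an inconsistent diagram (default TRUE).
#' @return an \code{adjacency_network}.
#' @export
build_network <- function(diagram, syn_type = c("chemical", "gap"),
                          quantitation = c("full", "polyad_split"),
                          polyad_weight = 0.5, drop_isolated = TRUE,
                          check_consistency = TRUE) {
  syn_type <- match.arg(syn_type)
  quantitation <- match.arg(quantitation)
  stopifnot(inherits(diagram, "wiring_diagram"))
  if (check_consistency) {
    v <- validate_consistency(diagram)
    v <- v[v$type == if (syn_type == "gap") "gap" else "chem", , drop = FALSE]
    if (syn_type == "gap") v <- v[v$kind != "gap count mismatch", , drop = FALSE]
    if (nrow(v))
      stop("diagram is inconsistent for type '", syn_type,
           "'; run validate_consistency() for the violation list")
  }
  nm <- diagram$neurons$name
  idx <- seq_along(nm)
  names(idx) <- nm
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  code <- if (syn_type == "gap") "gap" else "chem"
  r <- diagram$records[diagram$records$type == code, , drop = FALSE]
  if (nrow(r)) {
    w <- if (quantitation == "full") r$contacts else
      (r$contacts - r$polyadic) + polyad_weight * r$polyadic
    if (syn_type == "chemical") {
      A[cbind(idx[r$pre], idx[r$post])] <- w
    } else {
      # merge paired records: take the max over the two stated directions
      i <- pmin(idx[r$pre], idx[r$post])
      j <- pmax(idx[r$pre], idx[r$post])
      key <- paste(i, j)
      wm <- tapply(w, key, max)
      ij <- do.call(rbind, lapply(strsplit(names(wm), " "), as.integer))
      A[ij] <- wm
      A[ij[, c(2, 1), drop = FALSE]] <- wm
    }
  }
  if (drop_isolated) {
    keep <- rowSums(A) + colSums(A) > 0
    A <- A[keep, keep, drop = FALSE]
    nm <- nm[keep]
  }
  adjacency_network(A, nm, directed = (syn_type == "chemical"), quantitation)
}

#' Combine gap-junction and chemical networks into one directed network
#'
#' Binary mode treats a gap junction as a double-sided directed connection
#' and ignores weights: \code{A[i, j] = 1} iff there is a chemical
#' connection i to j or a gap junction between i and j. Weighted mode adds
#' multiplicities: \code{A[i, j] = m_chem(i -> j) + m_gap(i, j)}, the form
#' used for spectral dynamics of the combined network.
#'
#' @param gap undirected \code{adjacency_network}.
#' @param chem directed \code{adjacency_network}.
#' @param mode \code{"binary"} or \code{"weighted"}.
#' @return directed \code{adjacency_network}.
#' @export
combine_networks <- function(gap, chem, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  if (!identical(gap$names, chem$names))
    stop("gap and chemical networks must share the same neuron index; ",
         "align them (e.g. build both with drop_isolated = FALSE)")
  if (gap$directed) stop("gap network must be undirected")
  A <- if (mode == "binary") {
    ((chem$weights > 0) | (gap$weights > 0)) * 1
  } else {
    chem$weights + gap$weights
  }
  adjacency_network(A, gap$names, directed = TRUE,
                    quantitation = chem$quantitation)
}

#' Align two networks on a common neuron index
#'
#' Restricts both networks to the union (default) or intersection of their
#' name sets, inserting zero rows/columns for absent neurons under
#' \code{"union"}.
#'
#' @param a,b \code{adjacency_network}s.
#' @param join \code{"union"} or \code{"intersection"}.
#' @return list with elements \code{a} and \code{b} on the shared index.
#' @export
align_networks <- function(a, b, join = c("union", "intersection")) {
  join <- match.arg(join)
  nm <- if (join == "union") sort(union(a$names, b$names)) else
    sort(intersect(a$names, b$names))
  expand <- function(net) {
    A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
    keep <- intersect(nm, net$names)
    A[keep, keep] <- net$weights[keep, keep]
    adjacency_network(A, nm, net$directed, net$quantitation)
  }
  list(a = expand(a), b = expand(b))
}

#' Convert an adjacency network to an igraph graph
#'
#' Edge weights are stored in the \code{contacts} attribute.
#'
#' @param net an \code{adjacency_network}.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  mode <- if (net$directed) "directed" else "undirected"
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = mode,
                                           weighted = "contacts")
  g
}

#' Export a network as GraphML or a TSV edge list
#'
#' @param net an \code{adjacency_network}.
#' @param path output file path.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    A <- net$weights
    ij <- which(A > 0, arr.ind = TRUE)
    if (!net$directed) ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    df <- data.frame(pre = net$names[ij[, 1]], post = net$names[ij[, 2]],
                     contacts = A[ij])
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
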