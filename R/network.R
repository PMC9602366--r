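# Haplotype networks: epsilon-relaxed minimum spanning network and the
# median-joining construction of Bandelt, Forster & Roehl (1999).
# Determinism: nodes are always ordered observed-first by id, candidate
# links and medians are processed in lexicographic sequence order.

hamming <- function(x, y) sum(x != y)

seq_dist_matrix <- function(seqs) {
  mats <- strsplit(seqs, "", fixed = TRUE)
  k <- length(mats)
  d <- matrix(0L, k, k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- hamming(mats[[i]], mats[[j]])
    }
  }
  d
}

# epsilon-relaxed MSN over a set of sequences; returns an edge data.frame
msn_edges <- function(seqs, epsilon = 0) {
  k <- length(seqs)
  if (k == 1) return(data.frame(from = integer(0), to = integer(0),
                                weight = integer(0)))
  d <- seq_dist_matrix(seqs)
  comp <- seq_len(k)
  edges <- list()
  repeat {
    if (length(unique(comp)) == 1) break
    inter <- which(outer(comp, comp, "!=") & upper.tri(d), arr.ind = TRUE)
    dmin <- min(d[inter])
    sel <- inter[d[inter] <= dmin + epsilon, , drop = FALSE]
    # deterministic order: by weight, then endpoint indices
    sel <- sel[order(d[sel], sel[, 1], sel[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      i <- sel[r, 1]; j <- sel[r, 2]
      edges[[length(edges) + 1L]] <- c(i, j, d[i, j])
    }
    # merge all components touched at this level
    for (r in seq_len(nrow(sel))) {
      ci <- comp[sel[r, 1]]; cj <- comp[sel[r, 2]]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  e <- do.call(rbind, edges)
  e <- unique(data.frame(from = pmin(e[, 1], e[, 2]),
                         to = pmax(e[, 1], e[, 2]), weight = e[, 3]))
  e[order(e$weight, e$from, e$to), , drop = FALSE]
}

# quasi-median(s) of three equal-length sequences: per-column majority;
# columns with three distinct states keep all three (cartesian product)
quasi_medians <- function(s1, s2, s3, max_ambiguous = 4) {
  a <- strsplit(c(s1, s2, s3), "", fixed = TRUE)
  L <- length(a[[1]])
  cols <- vector("list", L)
  for (j in seq_len(L)) {
    st <- c(a[[1]][j], a[[2]][j], a[[3]][j])
    tab <- table(st)
    if (max(tab) >= 2) cols[[j]] <- names(tab)[which.max(tab)]
    else cols[[j]] <- sort(unique(st))
  }
  amb <- which(lengths(cols) > 1)
  if (length(amb) > max_ambiguous) {
    # cap the combinatorics: resolve surplus columns to the first state
    for (j in amb[-seq_len(max_ambiguous)]) cols[[j]] <- cols[[j]][1]
    amb <- amb[seq_len(max_ambiguous)]
  }
  if (length(amb) == 0) {
    return(paste(vapply(cols, `[`, "", 1), collapse = ""))
  }
  grid <- expand.grid(cols[amb], stringsAsFactors = FALSE)
  out <- character(nrow(grid))
  base <- vapply(cols, `[`, "", 1)
  for (r in seq_len(nrow(grid))) {
    v <- base
    v[amb] <- as.character(grid[r, ])
    out[r] <- paste(v, collapse = "")
  }
  sort(unique(out))
}

build_network <- function(seqs, kinds, freqs, pop_comp, epsilon, site_map) {
  e <- msn_edges(seqs, epsilon)
  positions <- lapply(seq_len(nrow(e)), function(r) {
    x <- strsplit(seqs[e$from[r]], "")[[1]]
    y <- strsplit(seqs[e$to[r]], "")[[1]]
    which(x != y)
  })
  nodes <- data.frame(node_id = names(seqs), sequence = unname(seqs),
                      kind = kinds, frequency = freqs,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 edges = data.frame(from = names(seqs)[e$from],
                                    to = names(seqs)[e$to],
                                    weight = e$weight,
                                    positions = vapply(positions, paste,
                                                       "", collapse = ","),
                                    stringsAsFactors = FALSE),
                 pop_composition = pop_comp,
                 epsilon = epsilon, site_map = site_map),
            class = "haplotype_network")
}

#' Minimum spanning network of haplotypes
#'
#' The union of all minimum spanning trees, relaxed by `epsilon`: links
#' between distinct components are admitted whenever their cost is within
#' `epsilon` of the minimal inter-component connection cost at that stage.
#'
#' @param ht A `haplotype_table` from [collapse_haplotypes()].
#' @param epsilon Non-negative integer relaxation (default 0).
#' @return A `haplotype_network`: `nodes` (id, sequence, kind, frequency),
#'   `edges` (from, to, weight, comma-separated 1-based differing
#'   positions), `pop_composition` (haplotype x population counts),
#'   `epsilon`.
#' @export
minimum_spanning_network <- function(ht, epsilon = 0) {
  seqs <- ht$sequences
  build_network(seqs, kinds = rep("observed", length(seqs)),
                freqs = rowSums(ht$counts)[names(seqs)],
                pop_comp = ht$counts, epsilon = epsilon,
                site_map = NULL)
}

#' Median-joining haplotype network
#'
#' Iterates: build the epsilon-relaxed minimum spanning network over the
#' current node set; for every triangle of mutually linked nodes compute
#' the quasi-median (per-column majority state, all combinations of the
#' three states where no majority exists); add novel medians; repeat until
#' closure. Finally, median vectors lying on no minimal observed-observed
#' path are removed (a documented simplification of Polzin-style maximum
#' parsimony pruning) and the network is rebuilt.
#'
#' @inheritParams minimum_spanning_network
#' @param max_iter Safety cap on closure iterations.
#' @return A `haplotype_network`; median vectors have ids `mv1, mv2, ...`
#'   and frequency 0.
#' @export
median_joining <- function(ht, epsilon = 0, max_iter = 20) {
  obs <- ht$sequences
  all_seqs <- obs
  for (iter in seq_len(max_iter)) {
    e <- msn_edges(all_seqs, epsilon)
    k <- length(all_seqs)
    adj <- matrix(FALSE, k, k)
    adj[cbind(e$from, e$to)] <- TRUE
    adj <- adj | t(adj)
    new_meds <- character(0)
    if (k >= 3) {
      trip <- utils::combn(k, 3)
      for (c_i in seq_len(ncol(trip))) {
        u <- trip[1, c_i]; v <- trip[2, c_i]; w <- trip[3, c_i]
        if (adj[u, v] + adj[u, w] + adj[v, w] < 3) next
        qm <- quasi_medians(all_seqs[u], all_seqs[v], all_seqs[w])
        new_meds <- c(new_meds, qm)
      }
    }
    new_meds <- sort(setdiff(unique(new_meds), all_seqs))
    if (length(new_meds) == 0) break
    ids <- paste0("mv", seq(sum(startsWith(names(all_seqs), "mv")) + 1,
                            length.out = length(new_meds)))
    all_seqs <- c(all_seqs, stats::setNames(new_meds, ids))
  }
  # prune median vectors on no minimal observed-observed path
  repeat {
    e <- msn_edges(all_seqs, epsilon)
    g <- igraph::graph_from_data_frame(
      data.frame(from = names(all_seqs)[e$from], to = names(all_seqs)[e$to],
                 weight = e$weight), directed = FALSE,
      vertices = names(all_seqs))
    sp <- igraph::distances(g, weights = igraph::E(g)$weight)
    med_ids <- names(all_seqs)[startsWith(names(all_seqs), "mv")]
    obs_ids <- setdiff(names(all_seqs), med_ids)
    drop <- character(0)
    for (m in med_ids) {
      on_path <- FALSE
      for (i in seq_along(obs_ids)) {
        for (j in seq_along(obs_ids)) {
          if (i >= j) next
          o1 <- obs_ids[i]; o2 <- obs_ids[j]
          if (abs(sp[o1, m] + sp[m, o2] - sp[o1, o2]) < 1e-9) {
            on_path <- TRUE; break
          }
        }
        if (on_path) break
      }
      if (!on_path) drop <- c(drop, m)
    }
    if (length(drop) == 0) break
    all_seqs <- all_seqs[setdiff(names(all_seqs), drop)]
  }
  kinds <- ifelse(startsWith(names(all_seqs), "mv"), "median_vector",
                  "observed")
  freqs <- ifelse(kinds == "observed",
                  rowSums(ht$counts)[names(all_seqs)], 0)
  build_network(all_seqs, kinds, freqs, pop_comp = ht$counts,
                epsilon = epsilon, site_map = NULL)
}

#' @export
print.haplotype_network <- function(x, ...) {
  nm <- sum(x$nodes$kind == "median_vector")
  cat("haplotype_network:", nrow(x$nodes) - nm, "observed haplotypes,",
      nm, "median vectors,", nrow(x$edges), "edges (epsilon =",
      x$epsilon, ")\n")
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#' @param net A `haplotype_network`.
#' @return An igraph graph with node/edge attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a haplotype network
#'
#' `edge_tsv` writes `<path>` with one edge per row (from, to, weight,
#' positions) preceded by commented node rows; `graphml` writes a GraphML
#' file via igraph. Node ordering is stable (observed first, then median
#' vectors, each in id order).
#'
#' @param net A `haplotype_network`.
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##nodes\tnode_id\tkind\tfrequency\tsequence", con)
  for (i in seq_len(nrow(net$nodes))) {
    writeLines(paste("#node", net$nodes$node_id[i], net$nodes$kind[i],
                     net$nodes$frequency[i], net$nodes$sequence[i],
                     sep = "\t"), con)
  }
  writeLines("from\tto\tweight\tpositions", con)
  if (nrow(net$edges) > 0) {
    utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back an edge-TSV network export
#' @param path File written by [export_network()] with `format =
#'   "edge_tsv"`.
#' @return A `haplotype_network` (without population composition).
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path)
  node_lines <- grep("^#node\t", lines, value = TRUE)
  nd <- do.call(rbind, strsplit(node_lines, "\t", fixed = TRUE))
  nodes <- data.frame(node_id = nd[, 2], sequence = nd[, 5], kind = nd[, 3],
                      frequency = as.numeric(nd[, 4]),
                      stringsAsFactors = FALSE)
  hdr <- which(lines == "from\tto\tweight\tpositions")
  edges <- if (hdr < length(lines)) {
    el <- do.call(rbind, strsplit(lines[(hdr + 1):length(lines)], "\t",
                                  fixed = TRUE))
    data.frame(from = el[, 1], to = el[, 2], weight = as.numeric(el[, 3]),
               positions = el[, 4], stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               positions = character(0))
  }
  structure(list(nodes = nodes, edges = edges, pop_composition = NULL,
                 epsilon = NA, site_map = NULL),
            class = "haplotype_network")
}
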