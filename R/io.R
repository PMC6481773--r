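# Readers and writers for the plain-text exchange formats: edge lists
# (TSV/SIF), GWAS tables, expression matrices, S-score panels, probeset and
# homolog maps, and GMT annotation sets. Gene symbols are uppercased at
# ingest (human-symbol convention); duplicates and self-loops are dropped
# with counts logged.

#' Read a PPI edge list (TSV or SIF)
#'
#' Two tab-separated gene-symbol columns per line (extra columns ignored);
#' the SIF dialect (`A relation B`) is auto-detected from a non-symbol-like
#' middle column on three-column input. Symbols are uppercased; duplicate
#' edges and self-loops are removed and logged.
#'
#' @param path file path.
#' @return undirected simple [igraph] graph.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # tolerate a header line such as "from<TAB>to"
  hdr <- c("from", "to", "source", "target", "gene1", "gene2", "gene_a",
           "gene_b", "protein1", "protein2", "node1", "node2")
  if (length(lines) &&
      all(tolower(strsplit(lines[1], "[\t ]+")[[1]][1:2]) %in% hdr))
    lines <- lines[-1]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed edge-list line ", which(nf < 2L)[1], " in ", path)
  # SIF dialect: exactly three fields and a lowercase relation in the middle
  is_sif <- all(nf >= 3L) &&
    all(vapply(parts, function(x) grepl("^[a-z_.-]+$", x[2]), NA))
  from <- toupper(vapply(parts, `[[`, "", 1L))
  to <- toupper(vapply(parts, function(x) x[[if (is_sif) 3L else 2L]], ""))
  self <- from == to
  if (any(self)) log_event("read_edge_list: dropped ", sum(self),
                           " self-loop(s)")
  from2 <- pmin(from[!self], to[!self]); to2 <- pmax(from[!self], to[!self])
  dup <- duplicated(paste(from2, to2, sep = "\r"))
  if (any(dup)) log_event("read_edge_list: dropped ", sum(dup),
                          " duplicate edge(s)")
  if (length(from2[!dup]) == 0L) stop("no edges left in ", path)
  igraph::graph_from_edgelist(cbind(from2[!dup], to2[!dup]),
                              directed = FALSE)
}

#' Write a graph as a two-column TSV edge list
#'
#' @param graph an [igraph] graph.
#' @param path output path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level GWAS table
#'
#' Headered TSV with columns `gene` and `p`.
#'
#' @param path file path.
#' @return named numeric vector of p-values (uppercased gene symbols).
#' @export
read_gwas_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "p") %in% names(df)))
    stop("GWAS table must have columns 'gene' and 'p': ", path)
  gene <- toupper(df$gene)
  if (anyDuplicated(gene))
    stop("duplicate gene symbol '", gene[duplicated(gene)][1], "' in ", path)
  p <- suppressWarnings(as.numeric(df$p))
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad))
    stop("invalid p-value in row ", bad[1], " ('", df$gene[bad[1]],
         "') of ", path)
  stats::setNames(p, gene)
}

#' Write a gene-level GWAS table
#'
#' @param gwas named numeric p-value vector.
#' @param path output path.
#' @export
write_gwas_table <- function(gwas, path) {
  utils::write.table(data.frame(gene = names(gwas), p = unname(gwas)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' Headered TSV, genes (or probesets) as rows, strains as columns; the first
#' column holds row identifiers.
#'
#' @param path file path.
#' @param region,condition labels attached to the panel.
#' @return an `expression_panel`.
#' @export
read_expression_matrix <- function(path, region = "NA",
                                   condition = "control") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- toupper(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row identifier '", ids[duplicated(ids)][1], "' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_panel(m, region = region, condition = condition)
}

#' Write an expression panel
#'
#' @param panel an `expression_panel`.
#' @param path output path.
#' @export
write_expression_matrix <- function(panel, path) {
  df <- data.frame(gene = rownames(panel$values), panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an S-score panel
#'
#' Headered TSV: first column probeset ids, remaining columns per-strain
#' S-scores.
#'
#' @param path file path.
#' @param region region label.
#' @return an `sscore_panel`.
#' @export
read_sscore_panel <- function(path, region = "NA") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate probeset id in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  sscore_panel(m, region = region)
}

#' Write an S-score panel
#'
#' @param panel an `sscore_panel`.
#' @param path output path.
#' @export
write_sscore_panel <- function(panel, path) {
  df <- data.frame(probeset = rownames(panel$scores), panel$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probeset-to-gene map
#'
#' Headered TSV with columns `probeset` and `gene`.
#'
#' @param path file path.
#' @return data.frame `probeset`, `gene` (gene symbols uppercased).
#' @export
read_probeset_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probeset", "gene") %in% names(df)))
    stop("probeset map must have columns 'probeset' and 'gene': ", path)
  df$gene <- toupper(df$gene)
  df
}

#' Read a homolog map
#'
#' Headered TSV with columns `source` and `target`.
#'
#' @param path file path.
#' @return data.frame `source`, `target` (both uppercased).
#' @export
read_homolog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df)))
    stop("homolog map must have columns 'source' and 'target': ", path)
  df$source <- toupper(df$source); df$target <- toupper(df$target)
  if (anyDuplicated(df$source)) stop("duplicate source symbol in ", path)
  df
}

#' Read GMT annotation sets
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members.
#'
#' @param path file path.
#' @return named list of gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1], " in ", path)
  stats::setNames(lapply(parts, function(x) toupper(x[-(1:2)])),
                  vapply(parts, `[[`, "", 1L))
}

#' Write GMT annotation sets
#'
#' @param sets named list of gene-symbol vectors.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a module's induced subgraph as GraphML
#'
#' @param genes module gene symbols.
#' @param wn a `weighted_network` (node/edge weights are attached as
#'   attributes).
#' @param path output path.
#' @export
write_module_graphml <- function(genes, wn, path) {
  sub <- igraph::induced_subgraph(wn$graph, genes)
  igraph::V(sub)$z <- unname(wn$z[igraph::V(sub)$name])
  if (igraph::ecount(sub) > 0) {
    el <- igraph::as_edgelist(sub, names = FALSE)
    ids <- match(igraph::V(sub)$name, wn$genes)
    ein <- vapply(seq_len(nrow(el)), function(e) {
      a <- ids[el[e, 1]]; b <- ids[el[e, 2]]
      which((wn$edges[, 1] == a & wn$edges[, 2] == b) |
              (wn$edges[, 1] == b & wn$edges[, 2] == a))[1]
    }, 0L)
    igraph::E(sub)$w <- wn$w[ein]
  }
  igraph::write_graph(sub, path, format = "graphml")
  invisible(path)
}

#' Read a module table written by [write_modules()]
#'
#' @param path file path.
#' @return `ew_module_list`.
#' @export
read_modules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mods <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(seed = df$seed[i],
                   genes = strsplit(df$genes[i], ";", fixed = TRUE)[[1]],
                   k = df$k[i], m = df$m[i], S_m = df$S_m[i],
                   S_n = df$S_n[i],
                   p = if ("p" %in% names(df)) df$p[i] else NULL,
                   q = if ("q" %in% names(df)) df$q[i] else NULL),
              class = "ew_module")
  })
  structure(mods, class = "ew_module_list")
}

#' Write a module table
#'
#' @param modules an `ew_module_list`.
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  utils::write.table(modules_to_table(modules), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
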