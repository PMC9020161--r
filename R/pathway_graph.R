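#' Parse a single pathway file into a pathway record
#'
#' Reads one pathway as a signed directed edge list. Two dialects are
#' supported: `edge_tsv`, a three-column tab-separated file
#' (`source<TAB>target<TAB>sign`, `#` comments allowed, sign in `{-1, +1}`);
#' and `kgml_subset`, a reduced KGML reader that extracts only gene-gene
#' relations whose subtype is `activation` (+1) or `inhibition` (-1).
#'
#' Self-loops are dropped (with a message) and duplicate identical edges are
#' collapsed. Unknown sign tokens are a parse error naming the line.
#'
#' @param path Path to the pathway file.
#' @param dialect Either `"edge_tsv"` or `"kgml_subset"`.
#' @param pathway_id Identifier for the pathway; defaults to the file stem.
#' @return An object of class `pathway_record`: a list with `pathway_id`,
#'   `name`, and `edges` (data.frame with columns `source`, `target`,
#'   `sign`).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("# demo", "A\tB\t1", "B\tC\t-1"), f)
#' p <- parse_pathway_file(f)
#' nrow(p$edges)  # 2
#' @seealso [build_ughp()]
#' @export
parse_pathway_file <- function(path, dialect = c("edge_tsv", "kgml_subset"),
                               pathway_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pathway file not found: ", path)
  pathway_id <- pathway_id %||% sub("\\.[^.]*$", "", basename(path))

  edges <- switch(dialect,
    edge_tsv = .parse_edge_tsv(path),
    kgml_subset = .parse_kgml_subset(path)
  )
  if (nrow(edges) == 0L) stop("pathway file has no edges: ", path)

  self <- edges$source == edges$target
  if (any(self)) {
    message(sum(self), " self-loop(s) dropped from pathway ", pathway_id)
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("pathway contains only self-loops: ", path)
  edges <- unique(edges)
  rownames(edges) <- NULL

  structure(list(pathway_id = pathway_id, name = pathway_id, edges = edges),
            class = "pathway_record")
}

.parse_edge_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty pathway file: ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop("malformed row at line ", idx[bad[1L]], " of ", path,
         " (expected 3 tab-separated fields)")
  }
  m <- do.call(rbind, parts)
  sign_chr <- trimws(m[, 3L])
  ok <- sign_chr %in% c("1", "+1", "-1")
  if (!all(ok)) {
    stop("invalid sign token '", sign_chr[!ok][1L], "' at line ",
         idx[!ok][1L], " of ", path, " (allowed: -1, 1, +1)")
  }
  data.frame(source = trimws(m[, 1L]), target = trimws(m[, 2L]),
             sign = ifelse(sign_chr == "-1", -1L, 1L),
             stringsAsFactors = FALSE)
}

# Minimal KGML reader: entries of type "gene" define node labels; relations
# with a subtype named "activation"/"inhibition" become signed edges. Entries
# naming several genes are expanded over the cartesian product. Everything
# else in KGML (compounds, groups, maplinks) is ignored.
.parse_kgml_subset <- function(path) {
  doc <- xml2::read_xml(path)
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  ids <- xml2::xml_attr(entries, "id")
  genes <- strsplit(xml2::xml_attr(entries, "name"), "\\s+")
  genes <- lapply(genes, function(g) sub("^hsa:", "", g))
  names(genes) <- ids

  rels <- xml2::xml_find_all(doc, ".//relation")
  rows <- list()
  for (r in rels) {
    e1 <- xml2::xml_attr(r, "entry1")
    e2 <- xml2::xml_attr(r, "entry2")
    if (!(e1 %in% ids) || !(e2 %in% ids)) next
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
    sgn <- if ("activation" %in% subs) 1L
           else if ("inhibition" %in% subs) -1L
           else next
    rows[[length(rows) + 1L]] <- expand.grid(
      source = genes[[e1]], target = genes[[e2]],
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    rows[[length(rows)]]$sign <- sgn
  }
  if (length(rows) == 0L) {
    return(data.frame(source = character(), target = character(),
                      sign = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read every pathway file in a directory
#'
#' @param dir Directory containing pathway files.
#' @param dialect Dialect passed to [parse_pathway_file()].
#' @param pattern Filename filter (default `"\\.tsv$"` for `edge_tsv`,
#'   `"\\.xml$"` for `kgml_subset`).
#' @return List of `pathway_record` objects.
#' @export
read_pathway_dir <- function(dir, dialect = c("edge_tsv", "kgml_subset"),
                             pattern = NULL) {
  dialect <- match.arg(dialect)
  pattern <- pattern %||% if (dialect == "edge_tsv") "\\.tsv$" else "\\.xml$"
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no pathway files found in ", dir)
  lapply(files, parse_pathway_file, dialect = dialect)
}

#' Build the unified global human pathway (UGHP) graph
#'
#' Takes the union over all pathways of all genes and all signed directed
#' gene-gene relations. The result is equivalent to a matrix
#' `UGHP[i, j]` in `{-1, 0, 1}`: +1 when some pathway asserts activation of
#' `j` by `i`, -1 for suppression, 0 when no pathway asserts a direct
#' relation. When two pathways disagree on the sign of the same ordered pair
#' the edge is kept (topology drives downstream scoring), its sign is stored
#' as +1, and the pair is recorded in `conflict_edges` with a warning.
#'
#' @param pathways Non-empty list of `pathway_record` objects.
#' @return An object of class `ughp`: list with `graph` (directed igraph,
#'   edge attributes `sign` and `conflict`), `nodes` (character vector),
#'   `edges` (data.frame `source`, `target`, `sign`, `conflict`) and
#'   `conflict_edges` (data.frame of disputed ordered pairs).
#' @examples
#' p1 <- list(pathway_id = "p1", name = "p1",
#'            edges = data.frame(source = "A", target = "B", sign = 1L))
#' class(p1) <- "pathway_record"
#' u <- build_ughp(list(p1))
#' u$nodes
#' @export
build_ughp <- function(pathways) {
  if (length(pathways) == 0L) stop("need at least one pathway")
  if (!all(vapply(pathways, inherits, logical(1), "pathway_record"))) {
    stop("all inputs must be pathway_record objects")
  }
  all_edges <- do.call(rbind, lapply(pathways, function(p) p$edges))
  key <- paste(all_edges$source, all_edges$target, sep = "\r")
  sgn <- tapply(all_edges$sign, key, function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else NA_integer_  # NA marks a sign conflict
  })
  uk <- names(sgn)
  st <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  conflict <- is.na(sgn)
  if (any(conflict)) {
    warning(sum(conflict), " edge(s) with conflicting sign across pathways;",
            " kept with sign +1 and flagged")
  }
  edges <- data.frame(source = st[, 1L], target = st[, 2L],
                      sign = ifelse(conflict, 1L, as.integer(sgn)),
                      conflict = as.integer(conflict),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = nodes))
  igraph::E(g)$sign <- edges$sign
  igraph::E(g)$conflict <- edges$conflict

  structure(list(graph = g, nodes = nodes, edges = edges,
                 conflict_edges = edges[edges$conflict == 1L,
                                        c("source", "target")],
                 cache = new.env(parent = emptyenv())),
            class = "ughp")
}

#' @export
print.ughp <- function(x, ...) {
  cat("Unified pathway graph:", length(x$nodes), "genes,",
      nrow(x$edges), "signed edges,",
      nrow(x$conflict_edges), "sign conflict(s)\n")
  invisible(x)
}

#' Export a UGHP to an edge TSV
#'
#' Writes columns `source`, `target`, `sign`, `conflict` (0/1).
#'
#' @param ughp A `ughp` object.
#' @param path Output file path.
#' @export
write_ughp <- function(ughp, path) {
  stopifnot(inherits(ughp, "ughp"))
  utils::write.table(ughp$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Hop-count distance matrix for the graph, cached per traversal mode.
# mode "all" ignores edge direction (default traversal); "out"/"in" follow /
# reverse direction. Cached in full only for graphs up to `max_cache` nodes.
.ughp_dist <- function(ughp, mode, from = NULL, max_cache = 3000L) {
  n <- length(ughp$nodes)
  key <- paste0("dist_", mode)
  if (n <= max_cache) {
    if (is.null(ughp$cache[[key]])) {
      ughp$cache[[key]] <- igraph::distances(ughp$graph, mode = mode)
    }
    d <- ughp$cache[[key]]
    if (is.null(from)) d else d[from, , drop = FALSE]
  } else {
    igraph::distances(ughp$graph, v = from %||% igraph::V(ughp$graph),
                      mode = mode)
  }
}

#' Nodes on all shortest paths between two genes
#'
#' Returns the union of nodes lying on every minimum-hop path from `source`
#' to `target` (unweighted). A node `v` is on some shortest path iff
#' `d(source, v) + d(v, target) == d(source, target)`. Unioning over all
#' shortest paths removes any tie-breaking nondeterminism.
#'
#' @param ughp A `ughp` object.
#' @param source,target Gene symbols; must be graph nodes.
#' @param directed If `FALSE` (default) edges are traversed ignoring
#'   direction; if `TRUE`, paths follow edge direction.
#' @return List with `nodes` (character vector) and `reachable` (logical).
#'   When `target` is unreachable, `nodes` is `{source, target}` and
#'   `reachable` is `FALSE`. `source == target` yields `{source}`.
#' @export
shortest_path_nodes <- function(ughp, source, target, directed = FALSE) {
  stopifnot(inherits(ughp, "ughp"))
  missing <- setdiff(c(source, target), ughp$nodes)
  if (length(missing) > 0L) {
    stop("gene(s) not in graph: ", paste(missing, collapse = ", "))
  }
  if (source == target) return(list(nodes = source, reachable = TRUE))
  mode_fwd <- if (directed) "out" else "all"
  mode_bwd <- if (directed) "in" else "all"
  ds <- .ughp_dist(ughp, mode_fwd, from = source)[1L, ]
  dt <- .ughp_dist(ughp, mode_bwd, from = target)[1L, ]
  dst <- ds[[target]]
  if (!is.finite(dst)) {
    return(list(nodes = sort(c(source, target)), reachable = FALSE))
  }
  on_path <- is.finite(ds) & is.finite(dt) & (ds + dt == dst)
  list(nodes = sort(names(ds)[on_path]), reachable = TRUE)
}
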