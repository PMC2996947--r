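#' @keywords internal
"_PACKAGE"

## Aspect vocabulary for knowledge-graph nodes. An entity (gene, protein,
## compound, process) can appear under several aspects; protein activities
## are distinct nodes from protein abundances and phosphorylation states.
KAM_ASPECTS <- c("rna_abundance", "protein_abundance", "protein_activity",
                 "protein_modification", "compound", "process")

KAM_SPECIES <- c("human", "rat", "mouse")

#' Canonical node identifier
#'
#' Nodes are identified by their (entity, aspect) pair; the key is
#' `"entity|aspect"`.
#'
#' @param entity,aspect character vectors.
#' @return character vector of node keys.
#' @export
node_key <- function(entity, aspect) paste(entity, aspect, sep = "|")

#' Construct a signed causal knowledge graph
#'
#' A `kam` ("knowledge assembly model") is a signed directed multigraph of
#' causal assertions among biological entities. Nodes are (entity, aspect)
#' pairs; aspects distinguish e.g. a protein's activity from its abundance or
#' its phosphorylation state. Edges carry a sign: `+1` (non-inverting, the
#' cause increases the effect) or `-1` (inverting). Contradictory edge pairs
#' (same endpoints, opposite sign) are permitted; they are what makes a
#' downstream polarity ambiguous.
#'
#' Duplicate `(source, target, sign)` triples are collapsed into a single edge
#' with their evidence strings merged. Self-loops (identical source and target
#' node) are rejected.
#'
#' @param nodes data.frame with columns `entity`, `aspect`.
#' @param edges data.frame with columns `source_entity`, `source_aspect`,
#'   `sign` (+1/-1), `target_entity`, `target_aspect`, and optionally
#'   `species` (human/rat/mouse, default human) and `evidence`
#'   (`;`-separated citation strings, default empty). May be `NULL` for an
#'   edgeless graph.
#' @param name character scalar naming the graph.
#' @return an object of class `kam` with canonically ordered `nodes` and
#'   `edges` data.frames.
#' @export
kam <- function(nodes, edges = NULL, name = "kam") {
  stopifnot(is.data.frame(nodes), all(c("entity", "aspect") %in% names(nodes)))
  nodes <- data.frame(entity = as.character(nodes$entity),
                      aspect = as.character(nodes$aspect),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(nodes$entity))) stop("node entity_id must be non-empty")
  bad <- setdiff(unique(nodes$aspect), KAM_ASPECTS)
  if (length(bad)) stop("unknown aspect token(s): ", paste(bad, collapse = ", "))
  keys <- node_key(nodes$entity, nodes$aspect)
  if (anyDuplicated(keys)) {
    nodes <- nodes[!duplicated(keys), , drop = FALSE]
    keys <- keys[!duplicated(keys)]
  }

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(source_entity = character(), source_aspect = character(),
                        sign = integer(), target_entity = character(),
                        target_aspect = character(), species = character(),
                        evidence = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    req <- c("source_entity", "source_aspect", "sign", "target_entity", "target_aspect")
    stopifnot(all(req %in% names(edges)))
    if (is.null(edges$species)) edges$species <- "human"
    if (is.null(edges$evidence)) edges$evidence <- ""
    edges <- edges[, c(req, "species", "evidence")]
    for (cc in setdiff(names(edges), "sign")) edges[[cc]] <- as.character(edges[[cc]])
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge sign must be +1 or -1; no unsigned edges")
    bad <- setdiff(unique(edges$species), KAM_SPECIES)
    if (length(bad)) stop("unknown species token(s): ", paste(bad, collapse = ", "))
    skey <- node_key(edges$source_entity, edges$source_aspect)
    tkey <- node_key(edges$target_entity, edges$target_aspect)
    miss <- setdiff(c(skey, tkey), keys)
    if (length(miss)) stop("edge endpoint(s) not in node set: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    self <- skey == tkey
    if (any(self)) stop("self-loop rejected: ", skey[which(self)[1]])
    ## collapse duplicate (source, target, sign) triples, merging evidence
    ekey <- paste(skey, tkey, edges$sign, sep = "\r")
    if (anyDuplicated(ekey)) {
      ev <- vapply(split(edges$evidence, ekey), function(e) {
        parts <- unique(unlist(strsplit(e[nzchar(e)], ";", fixed = TRUE)))
        paste(parts, collapse = ";")
      }, character(1))
      edges <- edges[!duplicated(ekey), , drop = FALSE]
      edges$evidence <- unname(ev[paste(node_key(edges$source_entity, edges$source_aspect),
                                        node_key(edges$target_entity, edges$target_aspect),
                                        edges$sign, sep = "\r")])
    }
  }

  ## canonical order -> load is order-independent
  no <- order(nodes$entity, nodes$aspect)
  nodes <- nodes[no, , drop = FALSE]
  eo <- order(edges$source_entity, edges$source_aspect,
              edges$target_entity, edges$target_aspect, edges$sign)
  edges <- edges[eo, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, name = name), class = "kam")
}

#' @export
print.kam <- function(x, ...) {
  cat(sprintf("<kam> %s: %d nodes, %d edges (%d inverting)\n", x$name,
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == -1L)))
  tab <- table(x$nodes$aspect)
  cat("  aspects:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Test two knowledge graphs for equality
#'
#' Compares node sets, edge sets and signs (and evidence/species annotation);
#' graph name is ignored. Both graphs are in canonical order by construction.
#'
#' @param a,b `kam` objects.
#' @return logical scalar.
#' @export
kam_equal <- function(a, b) {
  stopifnot(inherits(a, "kam"), inherits(b, "kam"))
  identical(a$nodes, b$nodes) && identical(a$edges, b$edges)
}

.parse_aspect <- function(tok, line) {
  if (!tok %in% KAM_ASPECTS)
    stop(sprintf("unknown aspect token '%s' at line %d", tok, line))
  tok
}

#' Read a signed causal graph from a tab-separated file
#'
#' Two dialects are supported:
#' \describe{
#'   \item{kamtsv}{Header row
#'     `source_entity source_aspect sign target_entity target_aspect species evidence`;
#'     sign tokens `+` and `-`; evidence is a `;`-joined list of citation
#'     strings and may be empty. A row whose `sign`, `target_entity` and
#'     `target_aspect` fields are all empty declares a bare (edgeless) node,
#'     so graphs with isolated nodes round-trip.}
#'   \item{sif_signed}{Three columns `source  activates|inhibits  target`
#'     where node names encode the aspect as `ENTITY.aspect`. A line with a
#'     single column declares a bare node. Species defaults to human,
#'     evidence is empty.}
#' }
#' Loading is deterministic and order-independent: the same rows in any order
#' produce an identical graph.
#'
#' @param path file path.
#' @param dialect `"kamtsv"` (default) or `"sif_signed"`.
#' @param name graph name; defaults to the file base name.
#' @return a [kam] object.
#' @export
load_kam <- function(path, dialect = c("kamtsv", "sif_signed"), name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]

  if (dialect == "kamtsv") {
    if (length(lines) == 0L) stop("empty kamtsv file: ", path)
    hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    want <- c("source_entity", "source_aspect", "sign", "target_entity",
              "target_aspect", "species", "evidence")
    if (!identical(hdr, want))
      stop("malformed kamtsv header at line 1: expected '",
           paste(want, collapse = " "), "'")
    body <- lines[-1]
    n <- length(body)
    src_e <- src_a <- tgt_e <- tgt_a <- spc <- evd <- character(n)
    sgn <- integer(n)
    is_node <- logical(n)
    for (i in seq_len(n)) {
      ln <- i + 1L
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      length(f) <- 7L
      f[is.na(f)] <- ""
      if (!nzchar(f[1])) stop(sprintf("malformed row at line %d: empty source_entity", ln))
      src_e[i] <- f[1]; src_a[i] <- .parse_aspect(f[2], ln)
      if (!nzchar(f[3]) && !nzchar(f[4]) && !nzchar(f[5])) {
        is_node[i] <- TRUE
        next
      }
      sgn[i] <- switch(f[3], "+" = 1L, "-" = -1L,
                       stop(sprintf("unknown sign token '%s' at line %d", f[3], ln)))
      tgt_e[i] <- f[4]; tgt_a[i] <- .parse_aspect(f[5], ln)
      if (!nzchar(f[4])) stop(sprintf("malformed row at line %d: empty target_entity", ln))
      spc[i] <- if (nzchar(f[6])) f[6] else "human"
      if (!spc[i] %in% KAM_SPECIES)
        stop(sprintf("unknown species token '%s' at line %d", f[6], ln))
      evd[i] <- f[7]
      if (node_key(src_e[i], src_a[i]) == node_key(tgt_e[i], tgt_a[i]))
        stop(sprintf("self-loop rejected at line %d: %s.%s", ln, src_e[i], src_a[i]))
    }
    ei <- !is_node
    nodes <- data.frame(entity = c(src_e, tgt_e[ei]),
                        aspect = c(src_a, tgt_a[ei]), stringsAsFactors = FALSE)
    edges <- data.frame(source_entity = src_e[ei], source_aspect = src_a[ei],
                        sign = sgn[ei], target_entity = tgt_e[ei],
                        target_aspect = tgt_a[ei], species = spc[ei],
                        evidence = evd[ei], stringsAsFactors = FALSE)
  } else {
    n <- length(lines)
    keep <- src <- tgt <- character(n)
    sgn <- integer(n)
    is_node <- logical(n)
    split_node <- function(tok, line) {
      m <- regmatches(tok, regexpr("\\.[^.]*$", tok))
      if (!length(m)) stop(sprintf("malformed node '%s' at line %d: no .aspect suffix", tok, line))
      asp <- sub("^\\.", "", m)
      list(entity = sub("\\.[^.]*$", "", tok), aspect = .parse_aspect(asp, line))
    }
    src_e <- src_a <- tgt_e <- tgt_a <- character(n)
    for (i in seq_len(n)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) == 1L) {
        nd <- split_node(f[1], i)
        src_e[i] <- nd$entity; src_a[i] <- nd$aspect
        is_node[i] <- TRUE
        next
      }
      if (length(f) != 3L) stop(sprintf("malformed row at line %d: expected 3 columns", i))
      sgn[i] <- switch(f[2], activates = 1L, inhibits = -1L,
                       stop(sprintf("unknown sign token '%s' at line %d", f[2], i)))
      s <- split_node(f[1], i); t <- split_node(f[3], i)
      src_e[i] <- s$entity; src_a[i] <- s$aspect
      tgt_e[i] <- t$entity; tgt_a[i] <- t$aspect
      if (node_key(s$entity, s$aspect) == node_key(t$entity, t$aspect))
        stop(sprintf("self-loop rejected at line %d: %s", i, f[1]))
    }
    ei <- !is_node
    nodes <- data.frame(entity = c(src_e, tgt_e[ei]),
                        aspect = c(src_a, tgt_a[ei]), stringsAsFactors = FALSE)
    edges <- data.frame(source_entity = src_e[ei], source_aspect = src_a[ei],
                        sign = sgn[ei], target_entity = tgt_e[ei],
                        target_aspect = tgt_a[ei],
                        species = rep("human", sum(ei)),
                        evidence = rep("", sum(ei)), stringsAsFactors = FALSE)
  }
  kam(nodes, edges, name = name)
}

#' Write a signed causal graph to a tab-separated file
#'
#' Inverse of [load_kam()]: `load_kam(write_kam(k, path), dialect)` returns a
#' graph equal to `k` under [kam_equal()]. Isolated nodes are written as bare
#' node rows (kamtsv: empty sign/target fields; sif_signed: single-column
#' lines).
#'
#' @param kam a [kam] object.
#' @param path output file path.
#' @param dialect `"kamtsv"` (default) or `"sif_signed"`. sif_signed drops
#'   species and evidence annotation.
#' @return `path`, invisibly.
#' @export
write_kam <- function(kam, path, dialect = c("kamtsv", "sif_signed")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(kam, "kam"))
  e <- kam$edges
  used <- unique(c(node_key(e$source_entity, e$source_aspect),
                   node_key(e$target_entity, e$target_aspect)))
  iso <- kam$nodes[!node_key(kam$nodes$entity, kam$nodes$aspect) %in% used, , drop = FALSE]
  if (dialect == "kamtsv") {
    hdr <- paste(c("source_entity", "source_aspect", "sign", "target_entity",
                   "target_aspect", "species", "evidence"), collapse = "\t")
    erows <- if (nrow(e)) paste(e$source_entity, e$source_aspect,
                                ifelse(e$sign > 0, "+", "-"), e$target_entity,
                                e$target_aspect, e$species, e$evidence, sep = "\t")
             else character()
    nrows <- if (nrow(iso)) paste(iso$entity, iso$aspect, "", "", "", "", "", sep = "\t")
             else character()
    writeLines(c(hdr, erows, nrows), path)
  } else {
    erows <- if (nrow(e)) paste(paste(e$source_entity, e$source_aspect, sep = "."),
                                ifelse(e$sign > 0, "activates", "inhibits"),
                                paste(e$target_entity, e$target_aspect, sep = "."),
                                sep = "\t")
             else character()
    nrows <- if (nrow(iso)) paste(iso$entity, iso$aspect, sep = ".") else character()
    writeLines(c(erows, nrows), path)
  }
  invisible(path)
}

## Precomputed adjacency index: node keys -> integer ids, out-edge list.
.kam_index <- function(kam) {
  keys <- node_key(kam$nodes$entity, kam$nodes$aspect)
  id <- seq_along(keys)
  names(id) <- keys
  e <- kam$edges
  si <- unname(id[node_key(e$source_entity, e$source_aspect)])
  ti <- unname(id[node_key(e$target_entity, e$target_aspect)])
  adj <- vector("list", length(keys))
  if (length(si)) {
    sp <- split(seq_along(si), si)
    for (nm in names(sp)) {
      rows <- sp[[nm]]
      adj[[as.integer(nm)]] <- cbind(target = ti[rows], sign = e$sign[rows])
    }
  }
  list(id = id, adj = adj, n = length(keys))
}

## Depth-bounded DFS over simple directed paths from root; records, for every
## node other than the root, which path-sign products (+1 / -1) are attainable.
.dn_search <- function(index, root_id, depth) {
  plus <- logical(index$n)
  minus <- logical(index$n)
  onpath <- logical(index$n)
  adj <- index$adj
  visit <- function(v, rem, sgn) {
    out <- adj[[v]]
    if (is.null(out)) return(invisible())
    for (k in seq_len(nrow(out))) {
      t <- out[k, 1L]
      if (onpath[t]) next          # simple paths only
      ns <- sgn * out[k, 2L]
      if (ns > 0L) plus[t] <<- TRUE else minus[t] <<- TRUE
      if (rem > 1L) {
        onpath[t] <<- TRUE
        visit(t, rem - 1L, ns)
        onpath[t] <<- FALSE
      }
    }
  }
  onpath[root_id] <- TRUE
  visit(root_id, as.integer(depth), 1L)
  list(plus = plus, minus = minus)
}

#' Downstream neighborhood of a node with attainable polarities
#'
#' Finds every node reachable from `root` by a directed simple path of at most
#' `depth` edges, together with the set of path-sign products attainable over
#' all such paths: `+1` only, `-1` only, or both (the node is reachable via
#' paths with contradictory polarity). The root itself is excluded. Simple
#' paths (no repeated node) bound the search in cyclic graphs.
#'
#' @param kam a [kam] object.
#' @param root_entity,root_aspect the root node.
#' @param depth maximum number of causal steps (default 2).
#' @return data.frame with columns `entity`, `aspect`, `plus`, `minus`
#'   (logical: is a path with that sign product attainable), one row per
#'   reachable node, in canonical node order.
#' @export
downstream_neighborhood <- function(kam, root_entity, root_aspect, depth = 2) {
  stopifnot(inherits(kam, "kam"), depth >= 1)
  index <- .kam_index(kam)
  rk <- node_key(root_entity, root_aspect)
  if (is.na(index$id[rk])) stop("root node not in graph: ", rk)
  res <- .dn_search(index, unname(index$id[rk]), depth)
  hit <- which(res$plus | res$minus)
  data.frame(entity = kam$nodes$entity[hit], aspect = kam$nodes$aspect[hit],
             plus = res$plus[hit], minus = res$minus[hit],
             stringsAsFactors = FALSE, row.names = NULL)
}

## All node ids reachable from `from_id` by directed paths of any length
## (sign-blind); used for the downstream-of-perturbation annotation.
.reachable_ids <- function(index, from_id) {
  seen <- logical(index$n)
  frontier <- from_id
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      out <- index$adj[[v]]
      if (is.null(out)) next
      t <- out[, 1L]
      t <- t[!seen[t]]
      seen[t] <- TRUE
      nxt <- c(nxt, t)
    }
    frontier <- unique(nxt)
  }
  which(seen)
}
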