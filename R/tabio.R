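#' @keywords internal
"_PACKAGE"

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIX <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                 family = "f", genus = "g", species = "s")

#' Validate a sample-by-feature count table
#'
#' Count tables are plain numeric matrices with samples as rows and features
#' as columns, both dimensions named. Cells must be non-negative integers and
#' ids unique.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, if valid; otherwise an error naming the offending
#'   row/column.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix (samples x features)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have sample (row) and feature (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample id: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate feature id: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(x < 0 | x != round(x) | is.na(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-integer count at sample '", rownames(x)[bad[1, 1]],
         "', feature '", colnames(x)[bad[1, 2]], "'")
  invisible(x)
}

#' Read / write a count table
#'
#' Tab-separated, samples as rows; first column `sample_id`, remaining
#' columns one per feature. `write_count_table()` then `read_count_table()`
#' is an exact round trip.
#'
#' @param path file path.
#' @param sample_ids optional character vector of expected sample ids. When
#'   the file's *column* header matches these ids (a transposed table) it is
#'   transposed on read; any other orientation mismatch is an error. Without
#'   `sample_ids` the file is taken as samples-in-rows.
#' @return an integer matrix, samples as rows.
#' @export
read_count_table <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs an id column plus >=1 feature")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in count table ", path)
  rownames(m) <- ids
  if (!is.null(sample_ids) && !any(ids %in% sample_ids)) {
    if (all(colnames(m) %in% sample_ids)) {
      m <- t(m)
    } else {
      stop("count table orientation does not match supplied sample ids; ",
           "refusing to guess (silent transposition hides real errors)")
    }
  }
  storage.mode(m) <- "integer"
  validate_count_table(m)
  m
}

#' @param table validated count matrix.
#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse QIIME-style lineage strings into a 7-rank taxonomy table
#'
#' Lineages are semicolon-delimited with single-letter rank prefixes
#' (`k__Bacteria; p__Firmicutes; ...; s__`). Missing trailing ranks become
#' empty strings.
#'
#' @param lineages character vector of lineage strings.
#' @return character matrix with columns kingdom..species.
#' @export
parse_lineage <- function(lineages) {
  out <- matrix("", nrow = length(lineages), ncol = 7,
                dimnames = list(NULL, RANKS))
  for (i in seq_along(lineages)) {
    parts <- trimws(strsplit(lineages[i], ";", fixed = TRUE)[[1]])
    parts <- sub("^[kpcofgs]__", "", parts)
    n <- min(length(parts), 7L)
    out[i, seq_len(n)] <- parts[seq_len(n)]
  }
  out
}

#' Read / write a feature taxonomy map
#'
#' Two tab-separated columns: `feature_id` and the 7-rank lineage string.
#'
#' @param path file path.
#' @return data.frame with `feature_id` plus one column per rank.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("taxonomy file needs feature_id and lineage columns")
  if (anyDuplicated(df[[1]]))
    stop("duplicate feature id in taxonomy: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  ranks <- parse_lineage(as.character(df[[2]]))
  data.frame(feature_id = as.character(df[[1]]), ranks,
             stringsAsFactors = FALSE)
}

#' @param tax taxonomy data.frame as returned by [read_taxonomy()].
#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- apply(tax[, RANKS, drop = FALSE], 1, function(r)
    paste(paste0(RANK_PREFIX, "__", r), collapse = "; "))
  utils::write.table(
    data.frame(feature_id = tax$feature_id, lineage = lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree over features
#'
#' Thin wrapper over [ape::read.tree()] that checks the result parses and is
#' rooted.
#'
#' @param path newick file.
#' @return an [ape] `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("unparseable newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick file: ", path)
  tree
}

#' Construct a clinical frame
#'
#' A clinical frame is a data.frame with `sample_id`, a `group` label
#' (`MCU`/`MUD`), and typed clinical variables. Variable kinds (binary,
#' count, continuous, categorical) are carried in the `"kinds"` attribute so
#' downstream statistics can dispatch on them. Binary variables are stored
#' as 0/1 integers.
#'
#' @param sample_id,group character vectors of equal length.
#' @param variables named list of equal-length vectors.
#' @param kinds named character vector giving the kind of each variable.
#' @return a `clinical_frame` data.frame.
#' @export
clinical_frame <- function(sample_id, group, variables = list(),
                           kinds = character()) {
  if (length(sample_id) != length(group))
    stop("sample_id and group lengths differ")
  if (anyDuplicated(sample_id)) stop("duplicate sample id in clinical frame")
  if (any(is.na(group))) stop("group label missing for some samples")
  df <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   stringsAsFactors = FALSE)
  for (v in names(variables)) {
    if (!v %in% names(kinds)) stop("no declared kind for variable '", v, "'")
    df[[v]] <- variables[[v]]
  }
  ok <- c("binary", "count", "continuous", "categorical")
  if (length(kinds) && !all(kinds %in% ok))
    stop("unknown variable kind: ",
         paste(setdiff(kinds, ok), collapse = ", "))
  attr(df, "kinds") <- kinds
  class(df) <- c("clinical_frame", "data.frame")
  df
}

#' @rdname clinical_frame
#' @param frame a clinical frame.
#' @export
clinical_kinds <- function(frame) attr(frame, "kinds")

#' Read / write a clinical metadata table
#'
#' Tab-separated with a header row followed by a `#types` row declaring the
#' kind of each variable column; `NA` marks missing values. A `group` column
#' is required.
#'
#' @param path file path.
#' @return a `clinical_frame`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("clinical file needs header and #types rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  types <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (!startsWith(types[1], "#types"))
    stop("second row must be the #types declaration")
  if (!"group" %in% header) stop("metadata missing group column")
  df <- utils::read.delim(text = lines[-2], stringsAsFactors = FALSE,
                          na.strings = "NA")
  vars <- setdiff(header, c("sample_id", "group"))
  kinds <- stats::setNames(types[match(vars, header)], vars)
  for (v in vars) {
    df[[v]] <- switch(kinds[[v]],
      binary = as.integer(df[[v]]),
      count = as.integer(df[[v]]),
      continuous = as.numeric(df[[v]]),
      categorical = as.character(df[[v]]),
      stop("unknown variable kind '", kinds[[v]], "' for '", v, "'"))
  }
  clinical_frame(df$sample_id, df$group,
                 variables = df[vars], kinds = kinds)
}

#' @rdname read_clinical
#' @param frame a clinical frame.
#' @export
write_clinical <- function(frame, path) {
  kinds <- clinical_kinds(frame)
  vars <- setdiff(names(frame), c("sample_id", "group"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", "group", vars), collapse = "\t"), con)
  writeLines(paste(c("#types", "group", unname(kinds[vars])), collapse = "\t"),
             con)
  body <- as.data.frame(frame)[, c("sample_id", "group", vars), drop = FALSE]
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Check that a count table's samples are covered by a clinical frame
#'
#' Samples present in the table but absent from the metadata are returned
#' (and warned about) rather than silently dropped.
#'
#' @param table count matrix.
#' @param frame clinical frame.
#' @return character vector of uncovered sample ids (possibly empty).
#' @export
check_sample_coverage <- function(table, frame) {
  missing <- setdiff(rownames(table), frame$sample_id)
  if (length(missing))
    warning("samples absent from metadata: ", paste(missing, collapse = ", "))
  invisible(missing)
}

#' Export a correlation network to a standard graph format
#'
#' Serializes node attributes (type, degree, betweenness, hub, authority —
#' whichever have been computed) and edge attributes (rho, p, p_adj, sign).
#'
#' @param net a `corr_net` (see [undirected_net()]).
#' @param path output file.
#' @param format one of `"graphml"`, `"gexf"`, `"edgelist-tsv"`.
#' @export
write_graph_file <- function(net, path,
                             format = c("graphml", "gexf", "edgelist-tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "corr_net"))
  g <- net$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist-tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_gexf(net, path)
  }
  invisible(path)
}

# Minimal GEXF 1.2 writer: nodes with typed attvalues, edges with weight=|rho|.
write_gexf <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  nodes <- net$nodes
  edges <- net$edges
  attrs <- setdiff(names(nodes), "id")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph defaultedgetype="',
    if (net$directed) "directed" else "undirected", '">')
  w('    <attributes class="node">')
  for (i in seq_along(attrs))
    w('      <attribute id="', i - 1, '" title="', esc(attrs[i]),
      '" type="string"/>')
  w('    </attributes>')
  w('    <nodes>')
  for (i in seq_len(nrow(nodes))) {
    w('      <node id="', esc(nodes$id[i]), '" label="', esc(nodes$id[i]),
      '">')
    w('        <attvalues>')
    for (j in seq_along(attrs))
      w('          <attvalue for="', j - 1, '" value="',
        esc(as.character(nodes[[attrs[j]]][i])), '"/>')
    w('        </attvalues>')
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges)))
      w('      <edge id="', i - 1, '" source="', esc(edges$u[i]),
        '" target="', esc(edges$v[i]), '" weight="', abs(edges$rho[i]), '"/>')
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}
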