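# Plain-text interchange: expression matrices, discrete datasets, the
# package's network format, and a reader for the common BIF dialect.

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a continuous expression matrix
#'
#' Delimited text (TSV or CSV, auto-detected): header row of sample IDs,
#' first column gene names, one gene per row.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene name '", dup[1L], "' (line ",
         which(genes == dup[1L])[2L] + 1L, ")")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  message("read expression matrix: ", nrow(m), " genes x ", ncol(m), " samples")
  m
}

#' Read a discrete categorical dataset
#'
#' Delimited text: header of variable names, one sample per row, entries are
#' state labels.
#'
#' @param path File path.
#' @param states Optional named list of state spaces (see
#'   [discrete_dataset()]).
#' @return A `discrete_dataset`.
#' @export
read_discrete_dataset <- function(path, states = NULL) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (anyDuplicated(names(df))) {
    stop("duplicate variable name '", names(df)[duplicated(names(df))][1L], "'")
  }
  message("read discrete dataset: ", nrow(df), " samples x ", ncol(df),
          " variables")
  discrete_dataset(df, states = states)
}

#' Write a discrete dataset
#' @param data A `discrete_dataset`.
#' @param path Output path (TSV).
#' @export
write_discrete_dataset <- function(data, path) {
  out <- as.data.frame(lapply(data, as.character), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in the package interchange format
#'
#' A line-oriented text document: the weight, one `variable` line per node
#' (state labels in order), one `edge` line per edge (with tag when not
#' "normal"), and per node a `cpt` block whose rows are keyed by
#' parent-state labels. `read_network()` inverts it exactly.
#'
#' @param bn A `bayesian_net`.
#' @param path Output path.
#' @export
write_network <- function(bn, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(..., collapse = " "), con)
  wl("# consensusbn network v1")
  wl(paste("weight", bn$weight))
  states <- bn_states(bn)
  for (v in bn$dag$nodes) wl(paste(c("variable", v, states[[v]]), collapse = " "))
  e <- bn$dag$edges
  for (i in seq_len(nrow(e))) {
    tag <- bn$dag$tags[i]
    wl(paste(c("edge", e[i, 1L], e[i, 2L],
               if (tag != "normal") tag), collapse = " "))
  }
  for (v in bn$dag$nodes) {
    cp <- bn$cpts[[v]]
    wl(paste(c("cpt", v, "|", cp$parents), collapse = " "))
    r <- cpt_cardinality(cp)
    m <- matrix(cp$prob, nrow = r)
    grid <- if (length(cp$parents)) {
      expand.grid(cp$states[cp$parents], KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE)
    } else data.frame(row.names = 1L)
    for (j in seq_len(ncol(m))) {
      key <- if (length(cp$parents)) unlist(grid[j, , drop = TRUE]) else character(0)
      wl(paste(c("row", key, ":",
                 formatC(m[, j], digits = 17, format = "g")), collapse = " "))
    }
  }
  invisible(path)
}

#' Read a network in the package interchange format
#'
#' @param path File path.
#' @return A `bayesian_net`; CPT rows failing to sum to 1 within 1e-6 are a
#'   validation error.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  weight <- 1L
  states <- list()
  node_order <- character(0)
  edges <- empty_edges()
  tags <- character(0)
  cpts <- list()
  cur <- NULL # current cpt: list(child, parents, rows)
  flush_cpt <- function() {
    if (is.null(cur)) return()
    child <- cur$child
    parents <- cur$parents
    r <- length(states[[child]])
    q <- if (length(parents)) prod(vapply(states[parents], length, integer(1))) else 1L
    m <- matrix(NA_real_, nrow = r, ncol = q)
    grid <- if (length(parents)) {
      expand.grid(states[parents], KEEP.OUT.ATTRS = FALSE,
                  stringsAsFactors = FALSE)
    } else NULL
    keys <- if (length(parents)) {
      apply(grid, 1L, paste, collapse = "\r")
    } else ""
    for (rw in cur$rows) {
      key <- paste(rw$key, collapse = "\r")
      j <- match(key, keys)
      if (is.na(j)) stop("cpt row for unknown configuration of '", child, "'")
      if (length(rw$p) != r) stop("cpt row length mismatch for '", child, "'")
      if (abs(sum(rw$p) - 1) > 1e-6) {
        stop("cpt row for '", child, "' sums to ", format(sum(rw$p)),
             ", not 1")
      }
      m[, j] <- rw$p
    }
    if (anyNA(m)) stop("incomplete CPT for '", child, "'")
    cards <- if (length(parents)) vapply(states[parents], length, integer(1)) else integer(0)
    cpts[[child]] <<- bn_cpt(child, parents, states, array(m, dim = c(r, cards)))
    cur <<- NULL
  }
  for (tk in toks) {
    kw <- tk[1L]
    if (kw == "weight") {
      weight <- as.integer(tk[2L])
    } else if (kw == "variable") {
      if (tk[2L] %in% node_order) stop("duplicate variable '", tk[2L], "'")
      node_order <- c(node_order, tk[2L])
      states[[tk[2L]]] <- tk[-(1:2)]
    } else if (kw == "edge") {
      edges <- rbind(edges, cbind(from = tk[2L], to = tk[3L]))
      tags <- c(tags, if (length(tk) >= 4L) tk[4L] else "normal")
    } else if (kw == "cpt") {
      flush_cpt()
      bar <- match("|", tk)
      parents <- if (bar < length(tk)) tk[(bar + 1L):length(tk)] else character(0)
      cur <- list(child = tk[2L], parents = parents, rows = list())
    } else if (kw == "row") {
      colon <- match(":", tk)
      key <- if (colon > 2L) tk[2L:(colon - 1L)] else character(0)
      p <- as.numeric(tk[(colon + 1L):length(tk)])
      cur$rows[[length(cur$rows) + 1L]] <- list(key = key, p = p)
    } else {
      stop("unrecognised line starting with '", kw, "'")
    }
  }
  flush_cpt()
  dag <- bn_dag(node_order, edges, tags)
  bayesian_net(dag, cpts, weight)
}

#' Read a network in BIF format
#'
#' A tolerant reader for the common flat BIF dialect (`variable` blocks with
#' discrete state lists, `probability` blocks with `table` rows or
#' per-configuration `( ... )` rows). Enough for the classic benchmark
#' network files.
#'
#' @param path File path.
#' @return A `bayesian_net` with weight 1.
#' @export
read_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)
  states <- list()
  var_m <- gregexpr("variable\\s+([^\\s{]+)\\s*\\{[^}]*type\\s+discrete\\s*\\[\\s*\\d+\\s*\\]\\s*\\{([^}]*)\\}", txt, perl = TRUE)
  for (m in regmatches(txt, var_m)[[1L]]) {
    name <- sub("variable\\s+([^\\s{]+).*", "\\1", m, perl = TRUE)
    st <- sub(".*discrete\\s*\\[\\s*\\d+\\s*\\]\\s*\\{([^}]*)\\}.*", "\\1", m, perl = TRUE)
    states[[name]] <- trimws(strsplit(st, ",")[[1L]])
  }
  if (!length(states)) stop("no variable blocks found in ", path)
  nodes <- names(states)
  edges <- empty_edges()
  cpts <- list()
  prob_m <- gregexpr("probability\\s*\\(([^)]*)\\)\\s*\\{([^}]*)\\}", txt, perl = TRUE)
  for (m in regmatches(txt, prob_m)[[1L]]) {
    head <- sub("(?s)probability\\s*\\(([^)]*)\\).*", "\\1", m, perl = TRUE)
    body <- sub("(?s)probability\\s*\\([^)]*\\)\\s*\\{([^}]*)\\}", "\\1", m,
                perl = TRUE)
    parts <- strsplit(head, "\\|")[[1L]]
    child <- trimws(parts[1L])
    parents <- if (length(parts) > 1L) {
      trimws(strsplit(parts[2L], ",")[[1L]])
    } else character(0)
    r <- length(states[[child]])
    cards <- vapply(states[parents], length, integer(1))
    q <- if (length(parents)) prod(cards) else 1L
    m_tab <- matrix(NA_real_, nrow = r, ncol = q)
    default_row <- NULL
    for (ln in strsplit(body, ";")[[1L]]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) next
      if (startsWith(ln, "table")) {
        p <- as.numeric(strsplit(sub("^table", "", ln), ",")[[1L]])
        m_tab[] <- p
      } else if (startsWith(ln, "default")) {
        default_row <- as.numeric(strsplit(sub("^default", "", ln), ",")[[1L]])
      } else if (startsWith(ln, "(")) {
        key <- trimws(strsplit(sub("^\\(([^)]*)\\).*", "\\1", ln), ",")[[1L]])
        p <- as.numeric(strsplit(sub("^\\([^)]*\\)", "", ln), ",")[[1L]])
        idx <- mapply(function(pr, k) match(k, states[[pr]]), parents, key)
        if (anyNA(idx)) stop("unknown parent state in BIF row: ", ln)
        mult <- cumprod(c(1L, cards[-length(cards)]))
        j <- 1L + sum((idx - 1L) * mult)
        m_tab[, j] <- p
      }
    }
    if (anyNA(m_tab) && !is.null(default_row)) {
      for (j in which(apply(m_tab, 2L, anyNA))) m_tab[, j] <- default_row
    }
    if (anyNA(m_tab)) stop("incomplete probability block for '", child, "'")
    cpts[[child]] <- bn_cpt(child, parents, states,
                            array(m_tab, dim = c(r, cards)))
    if (length(parents)) {
      edges <- rbind(edges, cbind(from = parents, to = child))
    }
  }
  miss <- setdiff(nodes, names(cpts))
  if (length(miss)) stop("no probability block for: ", paste(miss, collapse = ", "))
  bayesian_net(bn_dag(nodes, edges), cpts, 1L)
}
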