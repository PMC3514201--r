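# End-to-end orchestration: index starters, stream-map reads, error-correct,
# enumerate sub-starters, run the iterative extension phase, simplify and
# (optionally) write outputs.

#' Targeted micro-assembly around starter sequences
#'
#' Runs the full pipeline: (1) build a k-mer index over the starters;
#' (2) stream the reads (both strands) against it and accept placements
#' within `d` substitutions; (3) error-correct mapped reads by per-column
#' voting at threshold `t`; (4) enumerate each starter's sub-starters
#' (maximal perfect-consensus read subsets within distance `d`, covered at
#' least `c_min` everywhere); (5) extend every sub-starter iteratively in
#' both directions at zero mismatches, growing a rooted extension graph;
#' (6) simplify the graphs and, in sequence mode, extract the linear
#' consensus. Reads are never loaded wholesale: memory scales with the
#' mapped reads, not the read file.
#'
#' @param starters Path to a starter FASTA, or a named character vector of
#'   starter sequences.
#' @param reads Read input: FASTA/FASTQ path(s) (gzip allowed), a character
#'   vector of read sequences, or a tibble with `read_id`/`text`.
#' @param k Seed length (default 25; use smaller seeds for short reads).
#' @param d Maximum substitutions between a starter and its sub-starters
#'   (default 1).
#' @param c_min Minimum per-position read coverage of a sub-starter
#'   (default 2).
#' @param t Voting threshold for error correction (defaults to `c_min`).
#' @param max_iterations Extension iteration cap (default 10).
#' @param mode `"sequence"` (stop at divergences, output a consensus) or
#'   `"graph"` (follow every branch).
#' @param snp_merge In sequence mode, merge extension bundles differing by
#'   one substitution instead of stopping (default `FALSE`).
#' @param cap Maximum sub-starters per starter (default 100).
#' @param output_prefix When non-`NULL`, write outputs under this prefix:
#'   `<prefix>.fasta` (+ `.cov.tsv`) in sequence mode, one
#'   `<prefix>_<starter>_sub<i>.<dialect>` graph file per sub-starter in
#'   graph mode.
#' @param graph_format `"graphml"` (default) or `"xgmml"`.
#' @param chunk_records Reads per streamed chunk.
#' @return A `targeted_assembly` object: list with `summary` (per-starter
#'   tibble), `substarters` (named list of sub-starter tibbles), `graphs`
#'   (named list; per sub-starter a simplified `assembly_graph`),
#'   `consensus` (tibble of linear consensuses, sequence mode), `iterations`
#'   and `config`.
#' @examples
#' set.seed(1)
#' ref <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
#'   collapse = "")
#' sim <- simulate_reads(ref, read_length = 50, coverage = 30,
#'   error_rate = 0.01, seed = 7)
#' starter <- substr(ref, 181, 220)
#' res <- assemble_starters(c(roi = starter), sim$reads, k = 15, d = 0)
#' res$summary
#' @export
assemble_starters <- function(starters, reads, k = 25L, d = 1L, c_min = 2L,
                              t = c_min, max_iterations = 10L,
                              mode = c("sequence", "graph"),
                              snp_merge = FALSE, cap = 100L,
                              output_prefix = NULL,
                              graph_format = c("graphml", "xgmml"),
                              chunk_records = 20000L) {
  mode <- match.arg(mode)
  graph_format <- match.arg(graph_format)
  stopifnot(k >= 1L, d >= 0L, c_min >= 1L, t >= 1L, max_iterations >= 0L)
  if (is.character(starters) && length(starters) == 1L && file.exists(starters)) {
    starters <- load_starters(starters)
  } else {
    stopifnot(is.character(starters))
    if (is.null(names(starters)) || anyDuplicated(names(starters))) {
      stop("starters must carry unique names", call. = FALSE)
    }
    starters <- vapply(seq_along(starters), function(i) {
      sanitize_seq(starters[[i]], allow_n = FALSE,
        what = sprintf("starter '%s'", names(starters)[i]))
    }, character(1), USE.NAMES = FALSE) |> setNames(names(starters))
  }
  src <- read_source(reads)

  index <- build_kmer_index(starters, k)
  mapped_all <- map_reads(src, index, d = d, chunk_records = chunk_records)

  substarter_tbls <- list()
  graphs_out <- list()
  consensus_rows <- list()
  summary_rows <- list()
  total_iterations <- 0L

  for (sid in names(starters)) {
    s <- starters[[sid]]
    m <- mapped_all[mapped_all$target == sid, , drop = FALSE]
    n_raw <- nrow(m)
    if (n_raw > 0L) {
      pu <- build_pileup(m)
      m <- correct_mapped_reads(m, pu, t = t, target = s, d = d, min_len = k)
    }
    subs <- if (nrow(m) > 0L) {
      find_substarters(m, s, c_min = c_min, d = d, cap = cap)
    } else {
      empty_substarter_tbl()
    }
    substarter_tbls[[sid]] <- subs
    coherent <- is_read_coherent(subs)
    iters <- 0L
    if (coherent && max_iterations >= 0L) {
      phase <- run_extension_phase(subs, src, k = k, c_min = c_min, t = t,
        max_iterations = max_iterations, mode = mode, snp_merge = snp_merge,
        chunk_records = chunk_records)
      iters <- phase$iterations
      total_iterations <- total_iterations + iters
      for (i in seq_len(nrow(subs))) {
        gpair <- phase$graphs[[i]]
        ag <- join_sides(simplify_graph(gpair$left), simplify_graph(gpair$right))
        key <- sprintf("%s_sub%d", sid, i)
        graphs_out[[key]] <- ag
        if (mode == "sequence") {
          lin <- linear_consensus(ag)
          consensus_rows[[key]] <- tibble::tibble(
            starter = sid, substarter_index = i,
            distance = subs$distance[i],
            consensus = lin$consensus, coverage = list(lin$coverage))
        }
      }
    }
    summary_rows[[sid]] <- tibble::tibble(
      starter = sid,
      read_coherent = coherent,
      n_substarters = nrow(subs),
      n_mapped_reads = n_raw,
      iterations = iters
    )
  }

  consensus <- if (length(consensus_rows) > 0L) {
    dplyr::bind_rows(consensus_rows)
  } else {
    tibble::tibble(starter = character(0), substarter_index = integer(0),
      distance = integer(0), consensus = character(0), coverage = list())
  }

  if (!is.null(output_prefix)) {
    if (mode == "sequence") {
      write_consensus_fasta(consensus, paste0(output_prefix, ".fasta"))
    } else {
      for (key in names(graphs_out)) {
        write_graph_file(graphs_out[[key]],
          sprintf("%s_%s.%s", output_prefix, key, graph_format),
          dialect = graph_format)
      }
    }
  }

  structure(list(
    summary = dplyr::bind_rows(summary_rows),
    substarters = substarter_tbls,
    graphs = graphs_out,
    consensus = consensus,
    iterations = total_iterations,
    config = list(k = k, d = d, c_min = c_min, t = t,
      max_iterations = max_iterations, mode = mode, snp_merge = snp_merge,
      cap = cap, graph_format = graph_format),
    n_reads_seen = attr(mapped_all, "n_records")
  ), class = "targeted_assembly")
}

#' @export
print.targeted_assembly <- function(x, ...) {
  cat(sprintf(
    "<targeted_assembly> %d starter(s), %d read-coherent; mode=%s, k=%d, d=%d, c=%d\n",
    nrow(x$summary), sum(x$summary$read_coherent), x$config$mode,
    x$config$k, x$config$d, x$config$c_min))
  print(x$summary)
  invisible(x)
}

#' Per-starter summary of a targeted assembly
#'
#' @param x A `targeted_assembly`.
#' @param ... Unused.
#' @return Tibble with one row per starter: `read_coherent`,
#'   `n_substarters`, `n_mapped_reads`, `iterations`.
#' @export
tidy.targeted_assembly <- function(x, ...) x$summary

#' One-row overview of a targeted assembly run
#'
#' @param x A `targeted_assembly`.
#' @param ... Unused.
#' @return One-row tibble: starter counts, coherent counts, totals and the
#'   main parameters.
#' @export
glance.targeted_assembly <- function(x, ...) {
  tibble::tibble(
    n_starters = nrow(x$summary),
    n_read_coherent = sum(x$summary$read_coherent),
    n_substarters = sum(x$summary$n_substarters),
    n_mapped_reads = sum(x$summary$n_mapped_reads),
    n_reads_seen = x$n_reads_seen %||% NA_integer_,
    iterations = x$iterations,
    k = x$config$k, d = x$config$d, c_min = x$config$c_min,
    mode = x$config$mode
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot per-position coverage of sequence-mode consensuses
#'
#' @param result A `targeted_assembly` run in sequence mode.
#' @return A ggplot object (one facet per consensus record).
#' @export
plot_consensus_coverage <- function(result) {
  stopifnot(inherits(result, "targeted_assembly"))
  df <- dplyr::bind_rows(lapply(seq_len(nrow(result$consensus)), function(i) {
    cov <- result$consensus$coverage[[i]]
    tibble::tibble(
      record = sprintf("%s_sub%d", result$consensus$starter[i],
        result$consensus$substarter_index[i]),
      position = seq_along(cov) - 1L,
      coverage = cov)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$coverage)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~record, scales = "free_x") +
    ggplot2::labs(x = "position (nt)", y = "read coverage") +
    ggplot2::theme_minimal()
}
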