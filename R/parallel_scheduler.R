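#' Partition chromosomes across parallel workers
#'
#' Chromosomes are sorted by length (descending, ties broken by header
#' order) and greedily assigned, longest first, to the currently
#' least-loaded of `min(n_threads, #chromosomes)` groups, where load is the
#' summed chromosome length.  "Equally sized" therefore means balanced by
#' load, not by count — equal counts would pathologically unbalance genomes
#' with one giant chromosome.  When `n_threads` exceeds the number of
#' chromosomes, the surplus threads are handed out one at a time to
#' chromosomes in descending length order, wrapping around, as extra decoder
#' threads for multithreaded reading/decompression.
#'
#' Unindexed (e.g. unsorted) inputs cannot be region-fetched, so they force
#' the serial plan: one group holding all chromosomes in header order.
#'
#' @param chroms data frame with `name`, `length` in header order.
#' @param n_threads requested worker count, `>= 1`.
#' @param indexed whether the alignment file has a usable index.
#' @return An object of class `work_plan`: `groups` (list of chromosome-name
#'   vectors, one per worker), `decoder_threads` (named integer vector) and
#'   `chrom_order` (header order, used to reassemble results).
#' @export
build_plan <- function(chroms, n_threads, indexed) {
  n_threads <- as.integer(n_threads)
  if (length(n_threads) != 1L || is.na(n_threads) || n_threads < 1L)
    stop("n_threads must be a single integer >= 1")
  nm <- chroms$name
  dec <- stats::setNames(rep(1L, length(nm)), nm)
  if (!indexed || n_threads == 1L || length(nm) <= 1L) {
    plan <- list(groups = if (length(nm)) list(nm) else list(),
                 decoder_threads = dec, chrom_order = nm)
    class(plan) <- "work_plan"
    return(plan)
  }
  ord <- order(-as.numeric(chroms$length), seq_along(nm))
  n_groups <- min(n_threads, length(nm))
  groups <- rep(list(character()), n_groups)
  loads <- numeric(n_groups)
  for (i in ord) {
    g <- which.min(loads)                 # ties -> lowest group index
    groups[[g]] <- c(groups[[g]], nm[i])
    loads[g] <- loads[g] + chroms$length[i]
  }
  surplus <- n_threads - length(nm)
  if (surplus > 0L) {
    by_len <- nm[ord]
    recipients <- rep_len(by_len, surplus)  # wrap around in length order
    for (r in recipients) dec[r] <- dec[r] + 1L
  }
  plan <- list(groups = groups, decoder_threads = dec, chrom_order = nm)
  class(plan) <- "work_plan"
  plan
}

#' @export
print.work_plan <- function(x, ...) {
  cat(sprintf("<work_plan> %d group(s) over %d chromosome(s)\n",
              length(x$groups), length(x$chrom_order)))
  for (i in seq_along(x$groups))
    cat(sprintf("  group %d: %s\n", i, paste(x$groups[[i]], collapse = ", ")))
  invisible(x)
}

#' Execute a per-chromosome job under a work plan
#'
#' Runs `job(chrom_name)` for every scheduled chromosome.  With more than
#' one group on a unix platform the groups run in parallel forked workers
#' (share-nothing: each job must open its own file handles); otherwise
#' execution is serial.  Results are always reassembled in header
#' chromosome order regardless of completion order, so output is identical
#' for every thread count.  A failure in any worker aborts the whole run
#' with an error naming the chromosome.
#'
#' @param plan a [build_plan()] work plan.
#' @param job function of one argument (chromosome name).
#' @return Named list of job results in header chromosome order.
#' @export
run_plan <- function(plan, job) {
  stopifnot(inherits(plan, "work_plan"), is.function(job))
  if (!length(plan$chrom_order)) return(stats::setNames(list(), character()))
  run_group <- function(grp) {
    lapply(stats::setNames(grp, grp), function(ch) {
      tryCatch(job(ch), error = function(e)
        structure(list(chrom = ch, message = conditionMessage(e)),
                  class = "covdepth_worker_error"))
    })
  }
  parallel_ok <- length(plan$groups) > 1L && .Platform$OS.type == "unix"
  group_res <- if (parallel_ok) {
    parallel::mclapply(plan$groups, run_group,
                       mc.cores = length(plan$groups), mc.preschedule = FALSE)
  } else {
    lapply(plan$groups, run_group)
  }
  flat <- do.call(c, group_res)
  for (r in flat) {
    if (inherits(r, "covdepth_worker_error"))
      stop("worker for chromosome '", r$chrom, "' failed: ", r$message)
    if (inherits(r, "try-error"))
      stop("worker failed: ", as.character(r))
  }
  flat[plan$chrom_order]
}
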