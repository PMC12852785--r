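# Command-style drivers, CSV/JSON readers and writers, seed derivation and
# the benchmark loop that mirrors the simulation tables' structure.

#' Derive a per-run seed from a global seed
#'
#' Deterministic mixing of (global seed, run index, stream index) into a
#' 31-bit seed, so repetitions are reproducibly independent.
#'
#' @param seed global integer seed
#' @param run run index
#' @param stream sub-stream index (data, noise, ring randomness, ...)
#' @export
deriveSeed <- function(seed, run = 1L, stream = 0L) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  s <- (s * 48271) %% 2147483647
  s <- (s + run * 69621 + stream * 16807) %% 2147483647
  as.integer((s * 16807) %% 2147483647) + 1L
}

fmtNum <- function(x) formatC(x, digits = 17, format = "g")

writeNumericCSV <- function(x, path) {
  df <- as.data.frame(apply(as.matrix(x), 2, fmtNum))
  names(df) <- colnames(x, do.NULL = FALSE, prefix = "V")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

readNumericCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  as.matrix(vapply(df, as.numeric, numeric(nrow(df))))
}

#' Write a simulated scenario to CSV files
#'
#' Produces `data.csv` (the complete ground-truth matrix), `mask.csv`
#' (zero-one, 0 = missing), `outcome.csv` and `truth.json` (true weights
#' and scenario parameters) in `out`.  Values are written with 17
#' significant digits so write-then-read round-trips losslessly.
#'
#' @param scenario scenario id 1-6
#' @param n number of individuals
#' @param seed integer seed
#' @param out output directory (created if needed)
#' @param binaryOutcome use the binary-outcome variant
#' @return invisibly, the paths written
#' @export
cmdSimulate <- function(scenario, n = 500L, seed = 1L, out = ".",
                        binaryOutcome = FALSE) {
  spec <- scenarioSpec(scenario, n, seed = seed)
  ds <- if (binaryOutcome) genBinaryOutcome(spec) else genScenario(spec)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out, c("data.csv", "mask.csv", "outcome.csv",
                            "truth.json"))
  writeNumericCSV(ds@X, paths[1])
  maskDf <- as.data.frame(ds@mask)
  names(maskDf) <- colnames(ds@X)
  write.csv(maskDf, paths[2], row.names = FALSE, quote = FALSE)
  writeNumericCSV(matrix(ds@y, ncol = 1L, dimnames = list(NULL, "y")),
                  paths[3])
  jsonlite::write_json(
    list(theta = ds@theta, scenario = spec@scenarioId,
         nIndividuals = spec@nIndividuals, missingRate = spec@missingRate,
         mechanism = spec@mechanism, incompleteKind = spec@incompleteKind,
         seed = spec@seed),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a dataset written by [cmdSimulate()] (or user-supplied CSVs)
#'
#' @param dir directory holding `data.csv`, `mask.csv`, `outcome.csv` and
#'   optionally `truth.json`
#' @return list with `X`, `mask`, `y` and (if available) `theta`
#' @export
readDatasetCSV <- function(dir) {
  need <- file.path(dir, c("data.csv", "mask.csv", "outcome.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  X <- readNumericCSV(need[1])
  mask <- readNumericCSV(need[2])
  y <- as.numeric(readNumericCSV(need[3]))
  truthPath <- file.path(dir, "truth.json")
  theta <- if (file.exists(truthPath))
    as.numeric(jsonlite::read_json(truthPath, simplifyVector = TRUE)$theta)
  else NULL
  list(X = X, mask = mask, y = y, theta = theta)
}

#' Read a run configuration file (YAML or JSON)
#'
#' @param path configuration file; top-level keys mirror the arguments of
#'   [cmdRun()] (`mode`, `scenario`, `n`, `reps`, `k`, `seed`, `parties`,
#'   `noiseVar`, `out`)
#' @export
readRunConfig <- function(path) {
  if (grepl("[.](ya?ml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration needs the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

reorderInterceptFirst <- function(w) c(w[length(w)], w[-length(w)])

#' Run one imputation-and-analysis pipeline on a scenario
#'
#' Generates the scenario data, builds the task and executes the selected
#' pipeline (plaintext reference, secret-sharing, or partitioned
#' dataflow).  The data and the imputation-noise stream are derived from
#' `seed` identically in every mode, so modes can be compared with
#' injected identical noise; ring/backend randomness comes from an
#' independent dealer generator.
#'
#' @param scenario scenario id 1-6, or a list from [readDatasetCSV()]
#' @param n number of individuals (ignored when `scenario` is data)
#' @param mode `"plaintext"`, `"smc"` or `"mhe"`
#' @param k number of imputations
#' @param seed run seed
#' @param parties data-holding parties for the partitioned (`"mhe"`) mode;
#'   the secret-sharing engine itself always runs with two computing
#'   parties aided by the dealer (local probabilistic truncation is exact
#'   only in the two-party setting)
#' @param noiseVar imputation-noise variance
#' @param imputeSpec,finalSpec model templates (defaults per column kind)
#' @param binaryOutcome use the binary-outcome variant with a logistic
#'   final analysis
#' @return list: `result` ([MICEResult-class]), `dataset`, `metrics`
#'   (imputation and final-analysis error), `protocol` (triple and backend
#'   operation counts)
#' @export
runScenarioPipeline <- function(scenario, n = 500L,
                                mode = c("plaintext", "smc", "mhe"),
                                k = 5L, seed = 1L, parties = 2L,
                                noiseVar = 0.01,
                                imputeSpec = imputeSpecDefault(),
                                finalSpec = NULL, binaryOutcome = FALSE) {
  mode <- match.arg(mode)
  if (is.list(scenario)) {
    ds <- NULL
    X <- scenario$X; mask <- scenario$mask; y <- scenario$y
    theta <- scenario$theta
  } else {
    spec <- scenarioSpec(scenario, n, seed = deriveSeed(seed, 1L, 1L))
    ds <- if (binaryOutcome) genBinaryOutcome(spec) else genScenario(spec)
    X <- ds@X; mask <- ds@mask; y <- ds@y; theta <- ds@theta
  }
  task <- imputationTask(X * mask, mask, y, noiseVar = noiseVar)
  if (is.null(finalSpec))
    finalSpec <- regressionModel(if (binaryOutcome) "logistic" else "linear")
  set.seed(deriveSeed(seed, 1L, 2L))  # imputation-noise stream, mode-shared
  protocol <- list()
  if (mode == "plaintext") {
    res <- multipleImputeAnalyze(task, imputeSpec, finalSpec, k = k,
                                 mode = "plaintext")
  } else if (mode == "smc") {
    ctx <- dealerContext(deriveSeed(seed, 1L, 3L))
    res <- multipleImputeAnalyze(task, imputeSpec, finalSpec, k = k,
                                 mode = "smc", ctx = ctx)
    protocol <- list(triples = triplesIssued(ctx),
                     tripleShapes = ctx@state$triplesByShape)
  } else {
    ctx <- dealerContext(deriveSeed(seed, 1L, 3L))
    backend <- shareBackend(ctx)
    res <- mheMiceAnalyze(partitionRows(X * mask, parties),
                          partitionRows(y, parties),
                          partitionRows(mask, parties),
                          imputeSpec, finalSpec, k = k, backend = backend,
                          columnKinds = task@columnKinds,
                          noiseVar = noiseVar)
    protocol <- c(backendLog(backend), list(triples = triplesIssued(ctx)))
  }
  metrics <- list()
  if (!is.null(ds) || !is.null(theta)) {
    kindImp <- task@columnKinds[1L]
    if (length(res@imputed)) {
      impErr <- rowMeans(vapply(res@imputed, function(D)
        imputationError(D, X, mask, kindImp), numeric(2)))
      predErr <- rowMeans(vapply(res@imputed, function(D)
        predictionError(res@pooled, D, y,
                        if (binaryOutcome) "logistic" else "linear"),
        numeric(2)))
      metrics <- list(imputation = impErr, prediction = predErr)
    }
    if (!is.null(theta))
      metrics$thetaHat <- reorderInterceptFirst(res@pooled)
  }
  list(result = res, dataset = ds, metrics = metrics, protocol = protocol,
       seed = seed, mode = mode)
}

#' Run a pipeline repeatedly and aggregate the metrics
#'
#' Executes the selected pipeline `reps` times with derived seeds, writes
#' per-run and aggregate metrics (JSON) when `out` is given, and returns
#' them.  Failed runs (singular fits, calibration failures) are skipped
#' with a logged reason.
#'
#' @inheritParams runScenarioPipeline
#' @param reps number of repetitions
#' @param inputDir read the dataset from CSV files instead of simulating
#' @param out optional output path for the JSON report
#' @param verbose print progress
#' @return list with `runs` (per-run summaries) and `aggregate`
#' @export
cmdRun <- function(mode = "plaintext", scenario = 1L, n = 500L, reps = 1L,
                   k = 5L, seed = 1L, parties = 2L, noiseVar = 0.01,
                   inputDir = NULL, out = NULL, binaryOutcome = FALSE,
                   verbose = FALSE) {
  if (reps < 1L) stop("reps must be >= 1")
  input <- if (!is.null(inputDir)) readDatasetCSV(inputDir) else scenario
  runs <- vector("list", reps)
  for (r in seq_len(reps)) {
    runSeed <- deriveSeed(seed, r)
    pr <- tryCatch(
      runScenarioPipeline(input, n, mode, k = k, seed = runSeed,
                          parties = parties, noiseVar = noiseVar,
                          binaryOutcome = binaryOutcome),
      error = function(e) e)
    if (inherits(pr, "error")) {
      if (verbose) message("run ", r, " skipped: ", conditionMessage(pr))
      runs[[r]] <- list(run = r, seed = runSeed, ok = FALSE,
                        reason = conditionMessage(pr))
      next
    }
    runs[[r]] <- list(run = r, seed = runSeed, ok = TRUE,
                      pooled = pr$result@pooled,
                      pvalues = pr$result@pvalues,
                      thetaHat = pr$metrics$thetaHat,
                      imputation = pr$metrics$imputation,
                      prediction = pr$metrics$prediction,
                      protocol = pr$protocol)
    if (verbose) message("run ", r, "/", reps, " done (", mode, ")")
  }
  ok <- vapply(runs, `[[`, logical(1), "ok")
  agg <- list(mode = mode, scenario = if (is.list(input)) "file" else scenario,
              n = n, reps = reps, completed = sum(ok), k = k, seed = seed)
  okRuns <- runs[ok]
  if (length(okRuns)) {
    if (!is.null(okRuns[[1L]]$thetaHat)) {
      theta <- do.call(rbind, lapply(okRuns, `[[`, "thetaHat"))
      agg$theta <- as.list(thetaStats(theta, rep(1, ncol(theta))))
    }
    for (slot in c("imputation", "prediction")) {
      v <- lapply(okRuns, `[[`, slot)
      if (!is.null(v[[1L]]))
        agg[[slot]] <- as.list(rowMeans(do.call(cbind, v)))
    }
  }
  report <- list(aggregate = agg, runs = runs)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(report)
}

#' Benchmark scenarios across modes
#'
#' Runs each (scenario, n, mode) cell `reps` times with matched seeds,
#' computes coefficient bias/SD/rMSE against the true weights, the
#' imputation and final-analysis error, and the discrepancy count of each
#' mode against the plaintext base run with the same seeds, and emits one
#' table row per cell.
#'
#' @inheritParams cmdRun
#' @param scenarios scenario ids
#' @param ns sample sizes
#' @param modes execution modes (the plaintext base is always run)
#' @param out optional CSV path for the table
#' @return the benchmark table (data.frame)
#' @export
cmdBenchmark <- function(scenarios = 1L, ns = 500L,
                         modes = c("plaintext", "smc", "mhe"), reps = 2L,
                         k = 5L, seed = 1L, parties = 2L, out = NULL,
                         verbose = FALSE) {
  rows <- list()
  for (sc in scenarios) for (n in ns) {
    base <- cmdRun("plaintext", sc, n, reps = reps, k = k, seed = seed,
                   parties = parties, verbose = verbose)
    for (mode in unique(c("plaintext", modes))) {
      rep_ <- if (mode == "plaintext") base
        else cmdRun(mode, sc, n, reps = reps, k = k, seed = seed,
                    parties = parties, verbose = verbose)
      okB <- Filter(function(r) isTRUE(r$ok), base$runs)
      okT <- Filter(function(r) isTRUE(r$ok), rep_$runs)
      common <- intersect(vapply(okB, `[[`, 1L, "run"),
                          vapply(okT, `[[`, 1L, "run"))
      disc <- sum(vapply(common, function(ri) {
        b <- okB[[which(vapply(okB, `[[`, 1L, "run") == ri)]]
        t <- okT[[which(vapply(okT, `[[`, 1L, "run") == ri)]]
        discrepancyCount(list(pooled = b$pooled, pvalues = b$pvalues),
                         list(pooled = t$pooled, pvalues = t$pvalues))
      }, numeric(1)))
      agg <- rep_$aggregate
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, n = n, mode = mode,
        thetaBias = agg$theta$bias %||% NA_real_,
        thetaSd = agg$theta$sd %||% NA_real_,
        thetaRmse = agg$theta$rmse %||% NA_real_,
        finalErr1 = agg$prediction[[1L]] %||% NA_real_,
        finalErr2 = agg$prediction[[2L]] %||% NA_real_,
        discrepancies = disc,
        impErr1 = agg$imputation[[1L]] %||% NA_real_,
        impErr2 = agg$imputation[[2L]] %||% NA_real_,
        completed = agg$completed)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, out, row.names = FALSE)
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
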