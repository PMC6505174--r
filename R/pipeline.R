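#' Read breeding records from CSV
#'
#' Imports a breeding-record table into the canonical litter-record
#' schema. The canonical header is `dam_strain, sire_strain, dam_id,
#' sire_id, year, month, parity, litter_size, n_male, n_female` (or a
#' ready-made `batch` column in place of `year`/`month`); files with
#' other headers are adapted through `mapping`, a named list from
#' canonical names to the file's column names. Wean dates are mapped to
#' the 48-level batch index as consecutive year-months from the
#' earliest year-month present; dates beyond the 48-month window are
#' clamped to the window edge (with a warning) or dropped, per
#' `date_policy`.
#'
#' @param path CSV file path.
#' @param mapping named list/character vector, canonical name ->
#'   file column name; unmentioned columns are looked up by canonical
#'   name.
#' @param date_policy `"clamp"` (default) or `"drop"` for records
#'   outside the 48-month window.
#' @return A litter-record data frame (not yet validated; run
#'   [validate_records()]).
#' @export
read_breeding_csv <- function(path, mapping = NULL,
                              date_policy = c("clamp", "drop")) {
  date_policy <- match.arg(date_policy)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  get_col <- function(canon, required = TRUE) {
    nm <- if (!is.null(mapping) && canon %in% names(mapping))
      mapping[[canon]] else canon
    if (!nm %in% names(raw)) {
      if (required)
        stop("cannot map required column '", canon, "' (looked for '", nm,
             "'); available columns: ", paste(names(raw), collapse = ", "))
      return(NULL)
    }
    raw[[nm]]
  }
  rec <- data.frame(
    dam_strain = as.character(get_col("dam_strain")),
    sire_strain = as.character(get_col("sire_strain")),
    stringsAsFactors = FALSE
  )
  for (opt in c("dam_id", "sire_id")) {
    v <- get_col(opt, required = FALSE)
    rec[[opt]] <- if (is.null(v)) NA_character_ else as.character(v)
  }
  batch <- get_col("batch", required = FALSE)
  if (is.null(batch)) {
    year <- as.integer(get_col("year"))
    month <- as.integer(get_col("month"))
    ym <- year * 12L + (month - 1L)
    batch <- ym - min(ym, na.rm = TRUE) + 1L
    if (any(batch > 48L, na.rm = TRUE)) {
      if (date_policy == "clamp") {
        warning(sum(batch > 48L, na.rm = TRUE),
                " record(s) beyond the 48-month window clamped to batch 48")
        batch[batch > 48L] <- 48L
      } else {
        warning(sum(batch > 48L, na.rm = TRUE),
                " record(s) beyond the 48-month window dropped")
        keep <- is.na(batch) | batch <= 48L
        raw <- raw[keep, , drop = FALSE]
        rec <- rec[keep, , drop = FALSE]
        batch <- batch[keep]
      }
    }
  }
  rec$batch <- as.integer(batch)
  rec$parity <- as.integer(get_col("parity"))
  rec$litter_size <- as.integer(get_col("litter_size"))
  nm <- get_col("n_male", required = FALSE)
  nf <- get_col("n_female", required = FALSE)
  rec$n_male <- if (is.null(nm)) NA_integer_ else as.integer(nm)
  rec$n_female <- if (is.null(nf)) NA_integer_ else as.integer(nf)
  rec
}

#' Write breeding records to CSV in the canonical schema
#'
#' @param records a litter-record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_breeding_csv <- function(records, path) {
  cols <- intersect(c("dam_strain", "sire_strain", "dam_id", "sire_id",
                      "batch", "parity", "litter_size", "n_male",
                      "n_female"), names(records))
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

# Small deterministic config hash (31-ary polynomial over the serialized
# config text, mod 2^31 - 1; exact in double arithmetic)
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full diallel analysis pipeline
#'
#' End-to-end orchestration: validate (or simulate) breeding records,
#' fit the chosen diallel model, and write every standard output to
#' `out_dir`: the validated records and validation report, the posterior
#' draws (one scalar parameter per column, one retained draw per row)
#' with a JSON config sidecar, general and dam/sire effect-summary
#' tables, variance projections (general and dam/sire), expected cell
#' means, environmental ANOVA tables, sex-ratio tests, and a run log
#' naming the configuration hash. Stages run in order and any failure
#' aborts with the stage name; outputs written before the failure are
#' preserved.
#'
#' @param records litter records, a CSV path, or `NULL` to simulate
#'   from [default_truth()] under `seed`.
#' @param out_dir output directory (created if needed).
#' @param model `"ztp"`, `"gaussian"`, or `"binomial"`.
#' @param config a [fit_config()]; its seed also seeds the simulation
#'   when `records` is `NULL`.
#' @param mapping column mapping for CSV input (see
#'   [read_breeding_csv()]).
#' @param varp_include denominator classes beyond the diallel classes
#'   and residual (default batch and parity/order).
#' @param correction multiplicity correction for the sex-ratio tests.
#' @return Invisibly, a list with the fit, the varp summaries, and the
#'   paths written.
#' @export
run_pipeline <- function(records = NULL, out_dir, model = c("ztp", "gaussian",
                                                            "binomial"),
                         config = fit_config(seed = 1, n_iter = 5000,
                                             n_burn = 1000, thin = 4,
                                             n_chains = 2),
                         mapping = NULL,
                         varp_include = c("batch", "order"),
                         correction = "holm") {
  model <- match.arg(model)
  stopifnot(inherits(config, "fit_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  log_lines <- character(0)
  hash <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(name, df) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  log_add <- function(...) log_lines <<- c(log_lines, paste0(...))

  hash <- config_hash(config)
  log_add("diallelmm pipeline, package version ",
          as.character(utils::packageVersion("diallelmm")))
  log_add("config hash: ", hash)
  log_add("model: ", model, "; seed: ", config$seed)

  strains <- diallel_strains()
  records <- stage("import", {
    if (is.null(records)) {
      log_add("no input records: simulating from default_truth(seed)")
      tr <- default_truth(config$seed)
      simulate_sex(simulate_litters(tr, config$seed), tr, config$seed + 1L)
    } else if (is.character(records)) {
      read_breeding_csv(records, mapping)
    } else records
  })

  val <- stage("validate", validate_records(records))
  emit("records_validated.csv", val$records)
  emit("validation_report.csv", val$report)
  log_add("records kept: ", nrow(val$records), " of ",
          attr(val$report, "n_input"))

  fit <- stage("fit", switch(model,
    ztp = fit_ztp_diallel(val$records, strains, config),
    gaussian = fit_gaussian_diallel(val$records, strains, config),
    binomial = fit_binomial_diallel(val$records, strains, config)))

  stage("draws", {
    p <- file.path(out_dir, paste0("draws_", model, ".csv"))
    utils::write.csv(cbind(chain = fit$chain, as.data.frame(fit$draws)),
                     p, row.names = FALSE)
    paths <- c(paths, p)
    jsonlite::write_json(
      list(model = model, config = unclass(config), config_hash = hash,
           strains = as.character(strains)),
      file.path(out_dir, paste0("draws_", model, ".json")),
      auto_unbox = TRUE, pretty = TRUE)
  })

  stage("summaries", {
    emit("effect_summary.csv", effect_summary(fit))
    ds <- reparameterize_dam_sire(fit)
    emit("damsire_summary.csv", summarize_draws(cbind(ds$dam, ds$sire)))
  })

  varp <- varp_ds <- NULL
  if (model != "binomial") {
    vp <- stage("varp", {
      v1 <- compute_varp(fit, include = varp_include)
      v2 <- varp_dam_sire(fit, include = varp_include)
      emit("varp.csv", v1$summary)
      emit("varp_damsire.csv", v2$summary)
      emit("cell_means.csv", as.data.frame(expected_cell_means(fit)))
      list(v1, v2)
    })
    varp <- vp[[1L]]
    varp_ds <- vp[[2L]]
  }

  stage("env-tests", {
    env <- do.call(rbind, lapply(c("month", "year_month", "parity"),
                                 function(f)
                                   anova_oneway(val$records, f,
                                                inbred_only = (f != "parity"))))
    emit("env_tests.csv", env)
  })

  if ("n_male" %in% names(val$records) && !anyNA(val$records$n_male)) {
    stage("sexratio-tests", {
      emit("sexratio_strain.csv",
           sexratio_tests(val$records, "strain", correction))
      emit("sexratio_cross.csv",
           sexratio_tests(val$records, "cross", correction))
    })
  }

  log_add("outputs: ", paste(basename(paths), collapse = ", "))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(fit = fit, varp = varp, varp_dam_sire = varp_ds,
                 records = val$records, paths = paths,
                 config_hash = hash))
}
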