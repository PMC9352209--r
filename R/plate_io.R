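plate_roles <- c("coculture", "density-coculture", "donor-control",
                 "recipient-control", "transconjugant-control",
                 "mixed-control", "blank")
plating_targets <- c("donor-selective", "recipient-selective",
                     "transconjugant-selective")

#' Construct a microtiter plate record
#'
#' In the LDM plate assay, most wells hold parallel donor-recipient
#' cocultures whose turbidity under transconjugant selection is the
#' presence/absence readout; a few wells are sacrificed for dilution plating
#' (initial and final densities) and the rest are selection controls.
#'
#' @param wells Data frame with columns `well_id` (unique plate
#'   coordinates), `role` (one of coculture, density-coculture,
#'   donor-control, recipient-control, transconjugant-control,
#'   mixed-control, blank) and `turbid` (logical; required for cocultures
#'   and non-blank controls, `NA` for density wells and blanks).
#' @param platings Data frame of dilution-plating records with columns
#'   `well_id`, `target` (donor-/recipient-/transconjugant-selective),
#'   `timepoint` (`"initial"` or `"final"`), `colony_count`,
#'   `dilution_factor` (>= 1) and `plated_volume_ml` (> 0). May be empty.
#' @param culture_volume Coculture volume in ml; the volume correction used
#'   in the LDM estimate is `f = 1/culture_volume`.
#' @param t_tilde Incubation time of the assay (hr).
#' @param metadata Optional named list (e.g. date, replicate id).
#' @return An object of class `plate_data`.
#' @export
plate_data <- function(wells, platings = NULL, culture_volume, t_tilde,
                       metadata = list()) {
  if (is.null(platings)) {
    platings <- data.frame(well_id = character(0), target = character(0),
                           timepoint = character(0), colony_count = numeric(0),
                           dilution_factor = numeric(0),
                           plated_volume_ml = numeric(0))
  }
  problems <- validate_plate_tables(wells, platings, culture_volume, t_tilde)
  if (length(problems)) {
    stop(paste(c("invalid plate record:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(wells = wells, platings = platings,
                 culture_volume = culture_volume, t_tilde = t_tilde,
                 metadata = metadata),
            class = "plate_data")
}

validate_plate_tables <- function(wells, platings, culture_volume, t_tilde) {
  problems <- character(0)
  need <- c("well_id", "role", "turbid")
  if (!all(need %in% names(wells))) {
    return(sprintf("wells table must have columns %s",
                   paste(need, collapse = ", ")))
  }
  bad_role <- !wells$role %in% plate_roles
  if (any(bad_role)) {
    problems <- c(problems, sprintf("unknown role '%s' (well %s)",
                                    wells$role[bad_role],
                                    wells$well_id[bad_role]))
  }
  dup <- wells$well_id[duplicated(wells$well_id)]
  if (length(dup)) {
    problems <- c(problems,
                  sprintf("duplicate well_id %s", unique(dup)))
  }
  nocall <- wells$role == "coculture" & is.na(wells$turbid)
  if (any(nocall)) {
    problems <- c(problems, sprintf("coculture well %s has no turbidity call",
                                    wells$well_id[nocall]))
  }
  if (sum(wells$role == "coculture") < 1) {
    problems <- c(problems, "plate has no coculture wells")
  }
  if (nrow(platings)) {
    bad_t <- !platings$target %in% plating_targets
    if (any(bad_t)) {
      problems <- c(problems, sprintf("unknown plating target '%s'",
                                      unique(platings$target[bad_t])))
    }
    bad_tp <- !platings$timepoint %in% c("initial", "final")
    if (any(bad_tp)) {
      problems <- c(problems, sprintf("unknown timepoint '%s'",
                                      unique(platings$timepoint[bad_tp])))
    }
    if (any(platings$colony_count < 0, na.rm = TRUE)) {
      problems <- c(problems, "negative colony_count")
    }
    if (any(platings$dilution_factor < 1, na.rm = TRUE)) {
      problems <- c(problems, "dilution_factor below 1")
    }
    if (any(platings$plated_volume_ml <= 0, na.rm = TRUE)) {
      problems <- c(problems, "nonpositive plated_volume_ml")
    }
    orphan <- !platings$well_id %in% wells$well_id
    if (any(orphan)) {
      problems <- c(problems, sprintf("plating for unknown well %s",
                                      unique(platings$well_id[orphan])))
    }
    key <- with(platings, paste(well_id, target, timepoint))
    if (anyDuplicated(key)) {
      problems <- c(problems, sprintf("duplicate plating record %s",
                                      unique(key[duplicated(key)])))
    }
  }
  if (!is.numeric(culture_volume) || culture_volume <= 0) {
    problems <- c(problems, "culture_volume must be positive (ml)")
  }
  if (!is.numeric(t_tilde) || t_tilde <= 0) {
    problems <- c(problems, "t_tilde must be positive (hr)")
  }
  problems
}

#' @export
print.plate_data <- function(x, ...) {
  counts <- table(factor(x$wells$role, levels = plate_roles))
  cat(sprintf("LDM plate: %d wells, %g ml cocultures (f = %g), t~ = %g hr\n",
              nrow(x$wells), x$culture_volume, 1 / x$culture_volume,
              x$t_tilde))
  for (r in names(counts)) {
    if (counts[[r]] > 0) cat(sprintf("  %-24s %d\n", r, counts[[r]]))
  }
  cc <- x$wells$role == "coculture"
  if (any(cc)) {
    cat(sprintf("  nonturbid cocultures: %d/%d (p0_hat = %.3g)\n",
                sum(!x$wells$turbid[cc]), sum(cc),
                mean(!x$wells$turbid[cc])))
  }
  invisible(x)
}

#' Write a plate record to CSV
#'
#' The dialect is a plain CSV with a commented header carrying the plate
#' metadata, then one row per well (plating columns empty) and one row per
#' dilution-plating record (repeating the well's id, role and turbidity).
#' Columns: `well_id`, `role`, `turbid`, `target`, `timepoint`,
#' `colony_count`, `dilution_factor`, `plated_volume_ml`.
#'
#' @param plate A [plate_data()] object.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_plate <- function(plate, file) {
  stopifnot(inherits(plate, "plate_data"))
  w <- plate$wells
  well_rows <- data.frame(well_id = w$well_id, role = w$role,
                          turbid = w$turbid, target = NA_character_,
                          timepoint = NA_character_,
                          colony_count = NA_real_, dilution_factor = NA_real_,
                          plated_volume_ml = NA_real_)
  rows <- well_rows
  if (nrow(plate$platings)) {
    p <- plate$platings
    i <- match(p$well_id, w$well_id)
    plate_rows <- data.frame(well_id = p$well_id, role = w$role[i],
                             turbid = w$turbid[i], target = p$target,
                             timepoint = p$timepoint,
                             colony_count = p$colony_count,
                             dilution_factor = p$dilution_factor,
                             plated_volume_ml = p$plated_volume_ml)
    rows <- rbind(well_rows, plate_rows)
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# ldm-plate-csv v1", con)
  writeLines(sprintf("# culture_volume_ml: %.17g", plate$culture_volume), con)
  writeLines(sprintf("# t_tilde_hr: %.17g", plate$t_tilde), con)
  for (k in names(plate$metadata)) {
    writeLines(sprintf("# meta %s: %s", k, plate$metadata[[k]]), con)
  }
  utils::write.csv(rows, con, row.names = FALSE, na = "")
  invisible(file)
}

#' Parse a plate record from CSV
#'
#' Reads the dialect written by [write_plate()] and validates it, reporting
#' every violation (unknown role, duplicate well, missing turbidity call on
#' a coculture, malformed plating record) in one error.
#'
#' @param file Path to a plate CSV.
#' @return A [plate_data()] object.
#' @export
parse_plate <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  vol <- sub("^# culture_volume_ml:\\s*", "",
             grep("^# culture_volume_ml:", meta_lines, value = TRUE))
  tt <- sub("^# t_tilde_hr:\\s*", "",
            grep("^# t_tilde_hr:", meta_lines, value = TRUE))
  if (length(vol) != 1L || length(tt) != 1L) {
    stop("plate CSV must carry '# culture_volume_ml:' and '# t_tilde_hr:' ",
         "header lines", call. = FALSE)
  }
  metadata <- list()
  for (m in grep("^# meta ", meta_lines, value = TRUE)) {
    kv <- sub("^# meta ", "", m)
    key <- sub(":.*$", "", kv)
    metadata[[key]] <- sub("^[^:]*:\\s*", "", kv)
  }
  body <- lines[!grepl("^#", lines)]
  rows <- utils::read.csv(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = c(well_id = "character",
                                         role = "character",
                                         turbid = "logical",
                                         target = "character",
                                         timepoint = "character",
                                         colony_count = "numeric",
                                         dilution_factor = "numeric",
                                         plated_volume_ml = "numeric"))
  rows$target[rows$target == ""] <- NA_character_
  rows$timepoint[rows$timepoint == ""] <- NA_character_
  is_plating <- !is.na(rows$target)
  wells <- rows[!is_plating, c("well_id", "role", "turbid")]
  rownames(wells) <- NULL
  platings <- rows[is_plating, c("well_id", "target", "timepoint",
                                 "colony_count", "dilution_factor",
                                 "plated_volume_ml")]
  rownames(platings) <- NULL
  plate_data(wells, platings, as.numeric(vol), as.numeric(tt), metadata)
}

#' Check the selection controls of a plate
#'
#' After incubation under transconjugant selection the control wells must
#' behave: donor and recipient monocultures nonturbid (selection kills
#' them), the transconjugant monoculture turbid (selection permits it), and
#' the mixed-control cocultures -- donor plus recipient mixed after the
#' incubation, under selection -- nonturbid (no conjugation once selection
#' is applied). Any failure marks the plate's estimate untrusted; missing
#' control classes are reported as warnings, not errors.
#'
#' @param plate A [plate_data()] object.
#' @return A data frame (class `control_report`) with columns `class`,
#'   `status` (`"pass"`, `"fail"`, `"missing"`) and `message`; attribute
#'   `ok` is `TRUE` when no control failed.
#' @export
validate_controls <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  spec <- list(
    `donor-control` = list(expect = FALSE,
                           fail = "donor growth not suppressed by selection"),
    `recipient-control` = list(expect = FALSE,
                               fail = "recipient growth not suppressed by selection"),
    `transconjugant-control` = list(expect = TRUE,
                                    fail = "selection too strong: transconjugants did not grow"),
    `mixed-control` = list(expect = FALSE,
                           fail = "conjugation under selection not suppressed"))
  out <- do.call(rbind, lapply(names(spec), function(cls) {
    turbid <- plate$wells$turbid[plate$wells$role == cls]
    if (length(turbid) == 0) {
      data.frame(class = cls, status = "missing",
                 message = "control class absent from plate")
    } else if (all(turbid == spec[[cls]]$expect, na.rm = TRUE)) {
      data.frame(class = cls, status = "pass", message = "")
    } else {
      data.frame(class = cls, status = "fail", message = spec[[cls]]$fail)
    }
  }))
  if (any(out$status == "missing")) {
    warning(sprintf("control classes missing from plate: %s",
                    paste(out$class[out$status == "missing"],
                          collapse = ", ")), call. = FALSE)
  }
  structure(out, ok = !any(out$status == "fail"),
            class = c("control_report", "data.frame"))
}

#' Density from a dilution-plating record
#'
#' Standard colony-count arithmetic: density (cfu/ml) = colony count x
#' dilution factor / plated volume.
#'
#' @param colony_count Colonies counted (>= 0); vectorized.
#' @param dilution_factor Fold dilution before plating (>= 1).
#' @param plated_volume_ml Volume spread on the plate (ml, > 0).
#' @return Density in cfu/ml.
#' @examples
#' cfu_density(50, 1e5, 0.1)  # 5e7 cfu/ml
#' @export
cfu_density <- function(colony_count, dilution_factor, plated_volume_ml) {
  stopifnot(all(colony_count >= 0), all(dilution_factor >= 1),
            all(plated_volume_ml > 0))
  colony_count * dilution_factor / plated_volume_ml
}

# mean density over a plate's density wells for one target x timepoint
mean_plated_density <- function(plate, target, timepoint) {
  p <- plate$platings
  sel <- p$target == target & p$timepoint == timepoint
  if (!any(sel)) return(NA_real_)
  # density per well, then averaged on the linear scale
  d <- cfu_density(p$colony_count[sel], p$dilution_factor[sel],
                   p$plated_volume_ml[sel])
  mean(tapply(d, p$well_id[sel], mean))
}

#' LDM estimate from one plate
#'
#' One microtiter plate yields one LDM estimate: the transconjugant-free
#' fraction over the coculture wells, the initial and final donor and
#' recipient densities averaged over the density wells (per well, then
#' averaged on the linear scale), the incubation time, and the volume
#' correction `f = 1/culture_volume`, combined by [ldm_endpoint()]. The
#' control report is attached; a failing control leaves the estimate
#' computable but flagged untrusted, with a warning.
#'
#' @param plate A [plate_data()] object with donor- and recipient-selective
#'   platings at both timepoints.
#' @return A `conj_estimate` with extra fields `control_report` and
#'   `trusted`.
#' @export
plate_ldm_estimate <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  cc <- plate$wells$role == "coculture"
  p0_hat <- p0_mle(sum(!plate$wells$turbid[cc]), sum(cc))
  dens <- list(D0 = mean_plated_density(plate, "donor-selective", "initial"),
               R0 = mean_plated_density(plate, "recipient-selective", "initial"),
               Dt = mean_plated_density(plate, "donor-selective", "final"),
               Rt = mean_plated_density(plate, "recipient-selective", "final"))
  if (any(is.na(unlist(dens)))) {
    stop("plate lacks donor/recipient platings at both timepoints",
         call. = FALSE)
  }
  obs <- assay_observation(t_tilde = plate$t_tilde,
                           D0 = dens$D0, R0 = dens$R0,
                           Dt = dens$Dt, Rt = dens$Rt,
                           f = 1 / plate$culture_volume,
                           p0_hat = p0_hat, n_wells = sum(cc))
  est <- ldm_endpoint(obs)
  report <- validate_controls(plate)
  est$control_report <- report
  est$trusted <- isTRUE(attr(report, "ok"))
  if (!est$trusted) {
    warning("plate controls failed; estimate is untrusted", call. = FALSE)
  }
  est
}

#' SIM estimate from one plate
#'
#' End-point estimate from the plate's dilution-plating records alone:
#' initial and final donor, recipient and transconjugant densities averaged
#' across wells, then [sim_estimate()]. Requires transconjugant-selective
#' platings at the final timepoint.
#'
#' @param plate A [plate_data()] object.
#' @return A `conj_estimate`.
#' @export
plate_sim_estimate <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  Tt <- mean_plated_density(plate, "transconjugant-selective", "final")
  if (is.na(Tt)) {
    stop("plate lacks transconjugant-selective platings at the final ",
         "timepoint", call. = FALSE)
  }
  dens <- list(D0 = mean_plated_density(plate, "donor-selective", "initial"),
               R0 = mean_plated_density(plate, "recipient-selective", "initial"),
               Dt = mean_plated_density(plate, "donor-selective", "final"),
               Rt = mean_plated_density(plate, "recipient-selective", "final"))
  if (any(is.na(unlist(dens)))) {
    stop("plate lacks donor/recipient platings at both timepoints",
         call. = FALSE)
  }
  obs <- assay_observation(t_tilde = plate$t_tilde,
                           D0 = dens$D0, R0 = dens$R0,
                           Dt = dens$Dt, Rt = dens$Rt, Tt = Tt,
                           f = 1 / plate$culture_volume)
  sim_estimate(obs)
}

#' Design of a synthetic plate
#'
#' @param n_coculture Number of coculture wells (default 84, filling rows
#'   B-H of a 96-well plate).
#' @param n_density Number of density-measurement wells (default 3).
#' @param plated_volume_ml Volume plated per dilution record (default
#'   0.1 ml).
#' @param dilution `"auto"` (choose the smallest power of ten keeping the
#'   expected colony count at or below 300, the usual countable-plate
#'   limit) or a single explicit dilution factor applied to all records.
#' @param sim_plating If `TRUE`, also emit transconjugant-selective platings
#'   at the final timepoint (around the deterministic expectation of the
#'   mating model) so the plate supports [plate_sim_estimate()].
#' @return A list of class `plate_design`.
#' @export
plate_design <- function(n_coculture = 84, n_density = 3,
                         plated_volume_ml = 0.1, dilution = "auto",
                         sim_plating = FALSE) {
  stopifnot(n_coculture >= 1, n_coculture <= 84, n_density >= 1,
            n_density <= 3, plated_volume_ml > 0)
  structure(list(n_coculture = n_coculture, n_density = n_density,
                 plated_volume_ml = plated_volume_ml, dilution = dilution,
                 sim_plating = isTRUE(sim_plating)),
            class = "plate_design")
}

pick_dilution <- function(expected_count, dilution) {
  if (identical(dilution, "auto")) {
    10^max(0, ceiling(log10(expected_count / 300)))
  } else {
    as.numeric(dilution)
  }
}

#' Generate a synthetic LDM plate
#'
#' Simulates the readouts of one LDM plate under the stochastic mating
#' model: each coculture well is turbid with probability
#' `1 - p0_analytic(t_tilde, volume = culture_volume)` (the whole-well
#' first-event hazard, so smaller wells are more often transconjugant-free),
#' density wells receive Poisson colony counts around the deterministic
#' exponential expectations, and the control wells are emitted in their
#' expected states. A single transconjugant is assumed to always render its
#' well turbid (no establishment failure). Everything is drawn from the R
#' RNG seeded with `seed`, so the same seed reproduces the plate exactly.
#'
#' @param params A [rate_params()] object.
#' @param init An [inoculum()] with `T0 = 0`.
#' @param t_tilde Incubation time (hr).
#' @param culture_volume Coculture volume (ml), default 1.
#' @param design A [plate_design()].
#' @param seed Integer seed.
#' @return A [plate_data()] object.
#' @export
generate_plate_fixture <- function(params, init, t_tilde, culture_volume = 1,
                                   design = plate_design(), seed = 1) {
  stopifnot(inherits(params, "rate_params"), inherits(init, "inoculum"),
            inherits(design, "plate_design"), t_tilde > 0)
  if (init$T0 != 0) stop("plate fixtures assume T0 = 0", call. = FALSE)
  set.seed(seed)
  p_turbid <- 1 - p0_analytic(params, init, t_tilde, volume = culture_volume)

  all_ids <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  ctrl <- data.frame(
    well_id = c("A1", "A2", "A3", "A4", "A5"),
    role = c("donor-control", "recipient-control", "transconjugant-control",
             "mixed-control", "mixed-control"),
    turbid = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  dens_ids <- paste0("A", 5 + seq_len(design$n_density))
  dens <- data.frame(well_id = dens_ids, role = "density-coculture",
                     turbid = NA)
  blank_ids <- setdiff(paste0("A", 1:12), c(ctrl$well_id, dens_ids))
  blank <- if (length(blank_ids)) {
    data.frame(well_id = blank_ids, role = "blank", turbid = NA)
  }
  cc_ids <- all_ids[13:(12 + design$n_coculture)]
  cocult <- data.frame(well_id = cc_ids, role = "coculture",
                       turbid = runif(design$n_coculture) < p_turbid)
  wells <- rbind(ctrl, dens, blank, cocult)

  expected <- c(initial.donor = init$D0,
                initial.recipient = init$R0,
                final.donor = exponential_density(init$D0, params$psi_D,
                                                  t_tilde),
                final.recipient = exponential_density(init$R0, params$psi_R,
                                                      t_tilde))
  grid <- expand.grid(timepoint = c("initial", "final"),
                      target = c("donor-selective", "recipient-selective"),
                      well_id = dens_ids, stringsAsFactors = FALSE)
  pop <- ifelse(grid$target == "donor-selective", "donor", "recipient")
  if (design$sim_plating) {
    expected <- c(expected, final.transconjugant = ode_solve(
      params, init, c(0, t_tilde))$T[2])
    grid <- rbind(grid,
                  expand.grid(timepoint = "final",
                              target = "transconjugant-selective",
                              well_id = dens_ids, stringsAsFactors = FALSE))
    pop <- c(pop, rep("transconjugant", design$n_density))
  }
  dens_expect <- expected[paste(grid$timepoint, pop, sep = ".")]
  dil <- vapply(dens_expect * design$plated_volume_ml,
                pick_dilution, numeric(1), dilution = design$dilution)
  lambda <- dens_expect * design$plated_volume_ml / dil
  if (any(lambda > 1e4)) {
    stop("expected colony count exceeds 1e4: increase dilution",
         call. = FALSE)
  }
  platings <- data.frame(well_id = grid$well_id, target = grid$target,
                         timepoint = grid$timepoint,
                         colony_count = rpois(length(lambda), lambda),
                         dilution_factor = dil,
                         plated_volume_ml = design$plated_volume_ml)
  plate_data(wells, platings, culture_volume, t_tilde,
             metadata = list(origin = "synthetic", seed = seed))
}
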