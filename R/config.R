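#' Analysis configuration
#'
#' Bundles every geometric threshold of the pipeline. The 8 angstrom
#' alpha-carbon contact cutoff is the field's interface criterion; the
#' hydrogen-bond, salt-bridge and surface parameters are common literature
#' conventions, and the elastic-network values are the standard coarse
#' Cα-model choices. Every output artifact echoes the resolved
#' configuration so results are self-describing.
#'
#' @param contact_cutoff CA-CA contact cutoff (angstrom).
#' @param hbond_distance Donor-acceptor heavy-atom cutoff (angstrom).
#' @param hbond_angle Minimum D-H...A angle (degrees, used with hydrogens).
#' @param sb_cutoff Salt-bridge charged-atom cutoff (angstrom).
#' @param sasa_probe Solvent probe radius (angstrom).
#' @param sasa_points Sphere sample points per atom.
#' @param enm_cutoff Elastic-network spring cutoff (angstrom).
#' @param enm_gamma Elastic-network spring constant.
#' @param min_fraction Consensus presence threshold in (0, 1].
#' @param seed Integer seed for any randomized fixture generation.
#' @return A \code{run_config} list.
#' @export
run_config <- function(contact_cutoff = 8.0, hbond_distance = 3.5,
                       hbond_angle = 120, sb_cutoff = 4.0, sasa_probe = 1.4,
                       sasa_points = 960L, enm_cutoff = 12.0,
                       enm_gamma = 1.0, min_fraction = 1.0, seed = 1L) {
  cfg <- list(contact_cutoff = contact_cutoff,
              hbond_distance = hbond_distance, hbond_angle = hbond_angle,
              sb_cutoff = sb_cutoff, sasa_probe = sasa_probe,
              sasa_points = as.integer(sasa_points),
              enm_cutoff = enm_cutoff, enm_gamma = enm_gamma,
              min_fraction = min_fraction, seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "seed")]
  if (any(vapply(num, function(v) !is.numeric(v) || v <= 0, logical(1L)))) {
    stop("all configuration thresholds must be positive numbers")
  }
  if (cfg$min_fraction > 1) stop("min_fraction must be in (0, 1]")
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  invisible(x)
}

config_lines <- function(config) {
  vapply(names(config), function(k) paste0("# ", k, "=", format(config[[k]])),
         character(1L))
}

#' Write an interface profile to CSV + JSON
#'
#' The CSV holds one contact per row with the configuration echoed in
#' \code{#}-prefixed header lines; the JSON sidecar carries the counts,
#' buried surface area, composition and configuration, and round-trips via
#' \code{\link{read_profile_json}}.
#'
#' @param profile An \code{InterfaceProfile}.
#' @param csv_path,json_path Output paths (either may be \code{NULL} to
#'   skip).
#' @return Invisibly, the profile.
#' @export
write_profile <- function(profile, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(profile, "InterfaceProfile"))
  if (!is.null(csv_path)) {
    ct <- profile$contacts
    out <- data.frame(receptor_label = ct$receptor_label,
                      receptor_aa = ct$receptor_aa,
                      receptor_resnum = ct$receptor_resnum,
                      partner_label = ct$partner_label,
                      partner_aa = ct$partner_aa,
                      partner_resnum = ct$partner_resnum,
                      ca_distance = round(ct$ca_distance, 4L),
                      hbond = ct$hbond, saltbridge = ct$saltbridge,
                      stringsAsFactors = FALSE)
    con <- file(csv_path, "w")
    writeLines(config_lines(profile$config), con)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    payload <- list(complex_id = profile$complex_id,
                    n_contacts = nrow(profile$contacts),
                    n_hbonds = profile$n_hbonds,
                    n_saltbridges = profile$n_saltbridges,
                    buried_sasa = profile$buried_sasa,
                    composition = profile$composition,
                    config = unclass(profile$config),
                    contacts = profile$contacts)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(profile)
}

#' Read an interface profile back from its JSON sidecar
#'
#' @param path Path written by \code{\link{write_profile}}.
#' @return An \code{InterfaceProfile}.
#' @export
read_profile_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  contacts <- as.data.frame(p$contacts, stringsAsFactors = FALSE)
  class(contacts) <- c("ContactSet", "data.frame")
  comp <- lapply(p$composition, function(s)
    list(aa = unlist(s$aa), group = unlist(s$group)))
  prof <- list(complex_id = p$complex_id, contacts = contacts,
               n_hbonds = p$n_hbonds, n_saltbridges = p$n_saltbridges,
               buried_sasa = p$buried_sasa, composition = comp,
               config = do.call(run_config, p$config))
  class(prof) <- "InterfaceProfile"
  prof
}
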