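#' Read a port table CSV
#'
#' Expected header: \code{port_id}, \code{n_surveys}, one
#' \code{det_<species>} and one \code{nc_<species>} column per species,
#' optional \code{po_<species>} columns, and \code{mt}. Comma-separated,
#' UTF-8, header required. Invariants (0 <= det <= n_surveys, NC >= 0,
#' integer presence-only counts) are enforced with the offending row
#' named.
#'
#' @param path CSV file path.
#' @param pseudocount passed to \code{\link{prepare_covariates}}.
#' @return a \code{port_data} object (without a network; attach one from
#'   \code{\link{read_edge_list}} + \code{\link{port_network}}).
#' @export
read_port_table <- function(path, pseudocount = 1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("port_id", "n_surveys", "mt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("port table is missing column(s): ", paste(miss, collapse = ", "))
  det_cols <- grep("^det_", names(tab), value = TRUE)
  nc_cols <- grep("^nc_", names(tab), value = TRUE)
  po_cols <- grep("^po_", names(tab), value = TRUE)
  if (!length(det_cols)) stop("port table needs at least one det_<species> column")
  species <- sub("^det_", "", det_cols)
  if (!setequal(sub("^nc_", "", nc_cols), species))
    stop("nc_<species> columns must match det_<species> columns")
  roster <- as.character(tab$port_id)
  if (anyDuplicated(roster)) stop("duplicated port_id values")
  n_surveys <- as.integer(tab$n_surveys)
  bad <- which(is.na(n_surveys) | n_surveys < 1)
  if (length(bad)) stop("invalid n_surveys in row ", bad[1])
  det <- as.matrix(tab[paste0("det_", species)])
  colnames(det) <- species
  for (sp in species) {
    bad <- which(det[, sp] < 0 | det[, sp] > n_surveys)
    if (length(bad))
      stop("det_", sp, " outside [0, n_surveys] in row ", bad[1])
  }
  po <- NULL
  if (length(po_cols)) {
    po <- as.matrix(tab[po_cols])
    colnames(po) <- sub("^po_", "", po_cols)
    bad <- which(po < 0 | po != round(po), arr.ind = TRUE)
    if (nrow(bad)) stop("invalid presence-only count in row ", bad[1, 1])
  }
  nc <- as.matrix(tab[paste0("nc_", species)])
  colnames(nc) <- species
  bad <- which(nc < 0, arr.ind = TRUE)
  if (length(bad)) stop("negative nc in row ", bad[1])
  covariates <- prepare_covariates(nc, as.numeric(tab$mt),
                                   pseudocount = pseudocount)
  structure(list(roster = roster, n_surveys = n_surveys, det = det,
                 po = po, covariates = covariates, network = NULL,
                 species = species, truth = NULL),
            class = "port_data")
}

#' Write a port table CSV
#'
#' Inverse of \code{\link{read_port_table}} (the raw NC columns are
#' written, not the log transform).
#'
#' @param port_data a \code{port_data} object.
#' @param path output CSV path.
#' @export
write_port_table <- function(port_data, path) {
  sp <- port_data$species
  out <- data.frame(port_id = port_data$roster,
                    n_surveys = port_data$n_surveys)
  for (s in sp) out[[paste0("det_", s)]] <- port_data$det[, s]
  if (!is.null(port_data$po))
    for (s in sp) out[[paste0("po_", s)]] <- port_data$po[, s]
  for (s in sp) out[[paste0("nc_", s)]] <- port_data$covariates$nc[, s]
  out$mt <- port_data$covariates$mt
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a container-flow edge list CSV
#'
#' Header columns \code{origin,destination,volume}; one directed edge
#' per row, volumes in containers/year.
#'
#' @param path CSV path.
#' @return data.frame edge list.
#' @export
read_edge_list <- function(path) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  need <- c("origin", "destination", "volume")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    stop("edge list is missing column(s): ", paste(miss, collapse = ", "))
  edges
}

#' Write an edge list CSV
#' @param edges data.frame with origin, destination, volume.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.csv(edges[c("origin", "destination", "volume")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate raw presence records into per-port introduction counts
#'
#' Each primary (non-follow-up) record contributes one introduction
#' event to its observation port and to each distinct identified
#' domestic transit port on the container's path. Follow-up records —
#' re-observations of an introduction already on file — contribute
#' nothing beyond their parent. A port appearing more than once on one
#' record's path (or as both transit and observation port) counts once.
#'
#' @param records data.frame with columns \code{record_id},
#'   \code{species}, \code{port} (observation port),
#'   \code{transit_ports} (semicolon-separated ids, may be empty) and
#'   \code{follow_up_of} (parent record id, empty for primary records).
#' @param roster port roster (defines output order).
#' @param species species ids to tabulate (default: those present).
#' @return integer matrix ports x species of introduction-event counts.
#' @export
aggregate_presence_records <- function(records, roster, species = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("record_id", "species", "port", "transit_ports", "follow_up_of")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(species))
    species <- sort(unique(as.character(records$species)))
  counts <- matrix(0L, length(roster), length(species),
                   dimnames = list(roster, species))
  if (nrow(records) == 0) return(counts)
  fup <- as.character(records$follow_up_of)
  fup[is.na(fup)] <- ""
  is_follow <- fup != ""
  missing_parent <- setdiff(fup[is_follow], as.character(records$record_id))
  if (length(missing_parent))
    stop("follow-up record(s) reference missing parent: ",
         paste(missing_parent, collapse = ", "))
  primary <- records[!is_follow, , drop = FALSE]
  for (r in seq_len(nrow(primary))) {
    sp <- as.character(primary$species[r])
    if (!sp %in% species) next
    tp <- primary$transit_ports[r]
    tp <- if (is.na(tp) || tp == "") character(0)
          else trimws(strsplit(as.character(tp), ";")[[1]])
    ports <- unique(c(as.character(primary$port[r]), tp))
    unknown <- setdiff(ports, roster)
    if (length(unknown))
      stop("record ", primary$record_id[r],
           " references unknown port(s): ", paste(unknown, collapse = ", "))
    counts[ports, sp] <- counts[ports, sp] + 1L
  }
  counts
}

#' Rank ports by posterior introduction risk
#'
#' Posterior mean and central 95% credible interval of the
#' likelihood-level risk parameter (detection probability p for a survey
#' dataset, expected records lambda for presence-only) per port, ranked
#' in descending order of the posterior mean. Ties are broken by roster
#' order.
#'
#' @param samples a \code{posterior_samples} object.
#' @param dataset which dataset of the fit to rank (index or label).
#' @return data.frame of class \code{risk_report}: port, mean, q2.5,
#'   q97.5, rank.
#' @export
rank_ports <- function(samples, dataset = 1) {
  if (is.character(dataset)) dataset <- match(dataset, samples$labels)
  d <- samples$datasets[[dataset]]
  dm <- draw_matrix(samples)
  cn <- colnames(as.matrix(d$X))
  cols <- c(paste0("alpha_", d$label),
            if (length(cn)) paste0("beta_", d$label, "_", cn))
  eta <- dm[, cols, drop = FALSE] %*% t(cbind(1, as.matrix(d$X)))
  if (samples$model_type != "glm")
    eta <- eta + dm[, paste0("theta_", d$label, "[",
                             seq_len(samples$N), "]"), drop = FALSE]
  risk <- if (d$family == "binomial") stats::plogis(eta) else exp(eta)
  m <- colMeans(risk)
  qs <- apply(risk, 2, stats::quantile, probs = c(0.025, 0.975))
  ports <- if (!is.null(samples$network)) samples$network$ports
           else as.character(seq_along(m))
  out <- data.frame(port = ports, mean = m, q2.5 = qs[1, ], q97.5 = qs[2, ])
  out$rank <- rank(-out$mean, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("risk_report", "data.frame")
  out
}
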