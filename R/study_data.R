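#' Synthetic stand-in for the study's aggregated port table
#'
#' A deterministic, fully synthetic 65-port table whose marginal counts
#' match the published summary of the motivating survey: 975 survey
#' trials over 65 ports (13-20 each), 50 detections in total across the
#' two species, 11 ports positive for S. invicta in the survey (maximum
#' 8 detections of 19 surveys at the largest port, a 42.1% per-survey
#' rate), 11 ports positive for S. geminata (maximum 6 of 18, 33.3%),
#' and 115 presence-only introduction records in total (maxima 13 and 19
#' at the largest port). Everything else — which ports carry the counts,
#' the import volumes, temperatures and flow network — is invented, so
#' the object exercises the full input pipeline without reproducing any
#' real port's data.
#'
#' @param seed seed for the invented covariates and network volumes
#'   (counts are fixed, not random).
#' @return a \code{port_data} object (with \code{$network} attached).
#' @export
synthetic_study_data <- function(seed = 20170601) {
  N <- 65
  roster <- c("TYO", "YOK", "UKB", "OSK", sprintf("P%02d", 5:65))
  n_surveys <- c(19L, 18L, rep(15L, 56), rep(14L, 7))
  stopifnot(sum(n_surveys) == 975L)
  det_invicta <- integer(N)
  det_invicta[1:11] <- c(8L, 4L, 3L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)
  det_geminata <- integer(N)
  det_geminata[1:11] <- c(5L, 6L, 3L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)
  po_invicta <- integer(N)
  po_invicta[1:11] <- c(13L, 8L, 6L, 5L, 4L, 3L, 3L, 2L, 2L, 2L, 2L)
  po_geminata <- integer(N)
  po_geminata[1:13] <- c(19L, 9L, 7L, 6L, 5L, 4L, 3L, 3L, 2L, 2L, 2L, 2L, 1L)
  stopifnot(sum(det_invicta) + sum(det_geminata) == 50L,
            sum(po_invicta) + sum(po_geminata) == 115L)

  set.seed(seed)
  # import volumes decay from the hub ports; small noise, strictly > 0
  base <- exp(seq(log(2e5), log(60), length.out = N))
  nc <- cbind(invicta = round(base * exp(stats::rnorm(N, 0, 0.3))),
              geminata = round(base * exp(stats::rnorm(N, 0, 0.3))))
  mt <- round(seq(-4, 18, length.out = N) + stats::rnorm(N, 0, 1), 1)
  covariates <- prepare_covariates(nc, mt)

  # hub-and-spoke flows: spokes split between an eastern cluster
  # (TYO/YOK) and a western one (UKB/OSK)
  cluster <- c(1, 1, 2, 2, rep(c(1, 2), length.out = N - 4))
  edges <- list(); k <- 0
  add <- function(i, j, vol) {
    k <<- k + 1
    edges[[k]] <<- data.frame(origin = roster[i],
                              destination = roster[j], volume = vol)
  }
  add(1, 2, 45000); add(3, 4, 38000); add(1, 3, 6000); add(2, 4, 4000)
  for (s in 5:N) {
    hubs <- which(cluster[1:4] == cluster[s])
    for (h in hubs) add(h, s, round(stats::rlnorm(1, 6.5, 1.2)))
  }
  network <- port_network(do.call(rbind, edges), roster)

  structure(
    list(roster = roster, n_surveys = n_surveys,
         det = cbind(invicta = det_invicta, geminata = det_geminata),
         po = cbind(invicta = po_invicta, geminata = po_geminata),
         covariates = covariates, network = network,
         species = c("invicta", "geminata"), truth = NULL),
    class = "port_data")
}
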