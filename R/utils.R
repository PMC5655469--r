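# Deterministic per-individual RNG substreams.
#
# Each simulated individual draws from a stream keyed by (master seed,
# stratum id, individual index). The cohort arm (OA vs no-OA) is *not* part
# of the key: matched individuals in the two arms share their mortality
# uniforms (drawn first, fixed count), giving common-random-number pairing.
# The key is scrambled into a 31-bit seed by a multiplicative hash; all
# arithmetic stays below 2^53 so it is exact in doubles.
derive_seed <- function(master_seed, stratum_id, individual) {
  key <- (stratum_id - 1) * 2^21 + individual
  s <- (key * 2654435761 + (master_seed %% 2147483647) * 40503 + 17) %% 2147483647
  as.integer(s)
}

# independent stream for PSA parameter draws
derive_aux_seed <- function(master_seed, purpose = 1) {
  as.integer(((master_seed %% 2147483647) * 69069 + purpose * 104729 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric formatting used for all CSV output (deterministic, full precision)
write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
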