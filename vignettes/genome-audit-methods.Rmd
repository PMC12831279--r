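---
title: "Auditing genome builds against a curated transcript library: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing genome builds against a curated transcript library: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buildaudit)
```

## The problem

Machine-annotated genome builds of the same animal disagree wildly on how
many protein-coding genes exist and what their proteins look like. A manual
audit resolves this by holding a trusted, non-redundant library of
full-length transcripts and proteins against each build: every library gene
is searched in the build, the predicted protein is translated, and its
length is compared to the curated length as a checksum. Each gene then falls
into exactly one of six categories:

* `correct` — single locus, annotated, checksum passes, no premature stop,
  no frameshift, no ambiguous-N fill;
* `error_in_locus` — the locus exists but the product is wrong (indel,
  premature stop, wrong length, N-filled CDS);
* `split_multiple_loci` — the gene surfaces as two or more partial loci;
* `multiple_genes_one_locus` — one annotated locus carries two or more
  distinct protein products;
* `not_annotated` — the sequence is in the genome but no gene feature
  covers it;
* `sequence_not_present` — the sequence is missing from the assembly.

`buildaudit` implements that protocol as a reproducible pipeline, and —
because the audited quantity is only meaningful if the classifier can be
trusted — ships a synthetic-genome simulator that injects each error class
with a machine-readable ledger, so every classification rule is benchmarked
by injection and recovery.

## Synthetic truth sets

`generate_gene_models()` draws a library covering the structural classes an
audit must handle: multi-exon genes, true intronless genes (one exon),
CDS-intronless genes (CDS inside one exon, introns only in the UTRs),
selenoproteins (1–3 in-frame UGA codons recoded to Sec), adjacent
readthrough parent pairs, and single-exon retroelement ORFs. Defaults (CDS
150–600 codons, 2 + Poisson(3) exons, introns 200–800 bp, UTRs of 100–300 /
150–400 bp, 30% minus-strand genes) are compact but realistic gene anatomy;
they are deliberately small so a full injection-recovery run fits on a
desktop. Sequences are uniform-random nucleotides: real genomes have
repeats, GC structure and codon bias that random sequence does not, so
passing recovery here demonstrates the *logic* of the classifier, not its
robustness to repeat-rich loci (the `max_occ` repetitive-seed cap and the
retroelement class probe that direction, but a LINE-dense genome is out of
the simulator's reach).

`emit_genome()` places the models on chromosomes with random intergenic
spacers and canonical `GT..AG` introns; splicing the annotated exons back
out of the emitted genome reproduces each transcript byte for byte, which
is asserted in the tests.

`inject_build_errors()` corrupts a truth build under an `error_profile()`:

* coding indels either as a homogeneous Poisson process along the coding
  sequence with mean spacing `indel_spacing_bp`, or per-gene with
  probability `p_coding_indel` (length 1–2, placed at least 20 bp from exon
  boundaries — an edit hugging a splice junction may not change the spliced
  CDS at all and is therefore not a coding indel);
* per-gene loss of sequence (`p_missing_segment`), loss of annotation
  (`p_unannotated`), relocation of a genomic suffix block of exons to the
  far end of the chromosome (`p_split_locus`; only genes where some exon
  boundary moves 15–85% of the transcript are eligible, otherwise the gene
  falls back to an indel — relocating a sliver is not "gene appears in two
  loci"), merging of two adjacent errored genes into one annotated feature
  carrying both mRNAs (`p_merged_locus`), and truncation of a
  selenoprotein's annotated CDS at its first Sec UGA
  (`p_premature_stop_seleno`).

The per-gene probabilities partition a single uniform draw per gene, so the
probability that a gene is corrupted at all is exactly their sum — which is
what lets an end-to-end run dial in an expected error-free fraction
precisely. Merged pairs are formed only from adjacent genes that both drew
an error, preserving that independence. The two indel dialects mirror the
two conventions seen in practice: `n_fill` overwrites a ±10 bp window with
N and keeps the annotated protein length (the "correctly sized, low
quality" placeholder convention), `truncate` edits the bases and shifts all
downstream annotation coordinates so the corrupted build stays internally
consistent. With every rate zero the injector is the identity, asserted
byte-for-byte in the tests.

## Spliced mapping and indel detection

`map_transcript()` is a deterministic seed-and-chain spliced aligner:
exact k-mer anchors (default k = 16) against a reusable genome index,
clustered into candidate loci (genomic gaps above `max_locus_gap`, default
50 kb, separate loci), chained by dynamic programming, and merged into
co-linear blocks. Genomic gaps of at least `min_intron` (30 bp) with a
transcript-side gap of at most 4 bp are introns; junctions are nudged onto
`GT..AG` (smallest shift, leftmost on ties). Indel junctions are centred
within their placement-ambiguity run, the analogue of variant
normalisation, so reported positions are canonical. `detect_indels()` reads
events off the remaining gaps: build-side surplus is an insertion, deficit
a deletion, and an event is frameshifting exactly when it lies in the CDS
with length not divisible by 3.

Two numerical choices matter downstream. The reporting floor for a locus is
10% coverage at 85% identity — low enough that both halves of a split gene
surface (the split classifier needs the minor half). And the subject index
accepts a sampling `stride`: at stride *s* anchors blur by at most *s* − 1
bp at their ends while inter-anchor gap lengths stay exact, so event
*counts* are stride-insensitive; the indel-rate experiment uses stride 8
(with k = 24 to keep random collisions out of megabase-scale loci), while
the default stride is 1.

`pairwise_protein_align()` is optimal local (Smith–Waterman) alignment via
`Biostrings::pairwiseAlignment`, under BLOSUM62 extended so U (Sec) scores
as cysteine and X scores 0; tests check it against an independent
exhaustive dynamic-programming oracle.

## Classification

`classify_gene()` applies a fixed decision order (a)→(f): sequence present
(best coverage ≥ `c_present` = 0.30)? fragmented (≥2 loci, none ≥
`c_single` = 0.90, jointly ≥ 0.80)? multiple distinct products under the
overlapping annotated feature? annotated at all? checksum / premature-stop
/ frameshift / N-fill clean? The manual protocol implies but does not state
this precedence; fixing it makes the category exclusive and exhaustive,
which the tests assert. The thresholds separate "absent" from "fragmented"
cleanly on synthetic data and are exposed in `classify_params()`.

Translation is Sec-aware throughout: `translate_cds()` reads a UGA at a
declared Sec codon as U rather than a stop, so uncorrupted selenoproteins
are never flagged with the false premature stop that automatic pipelines
produce — the neutrality property is tested explicitly. Codons containing N
translate to X, so an N-filled CDS still yields the annotated protein
length: such a gene passes its checksum but is still `error_in_locus` with
`n_filled` evidence. The pseudogene flag is raised only for a premature
stop *not* attributable to an N fill — a sequence-confirmed stop rather
than a placeholder artifact; with a single annotated transcript per
synthetic gene this is the practical reading of requiring confirmation in
independent alignment paths. A frameshift is also recognised when the
annotated CDS's nucleotide length has shifted out of frame relative to the
curated CDS even if the alignment absorbed the edit near a junction.

`estimate_indel_rate()` turns detected events over surveyed coding bp into
bp-per-indel with an exact Poisson 95% interval (`stats::poisson.test`).

## The injection-recovery experiments

Two drivers reproduce the study-scale numbers end to end.

`indel_rate_experiment()` builds one truth set of 50 single-exon loci of
334,000 codons (50.1 Mb of coding sequence — the statistic is per-bp, so
few large loci and many small ones are equivalent and the former is far
cheaper), injects Poisson indels at 12,465 bp mean spacing under 100
seeds, re-maps every transcript to its corrupted locus, and estimates
bp-per-indel per seed. Two events closer than the anchor resolution
w = k + stride − 1 bp cannot be separated, so the estimator applies the
standard non-paralyzable dead-time correction from counting statistics —
surveyed bp minus n·w — before forming the rate; the residual bias (from
the rare merged pair whose opposite edits cancel, and from the ±4 bp
separation enforced between injected edits) is below 0.1%, far inside the
interval's ±3% half-width. Per seed, the exact Poisson interval covers the
injected spacing with its nominal ~95% probability; over any fixed block
of 100 seeds the covered count then carries binomial spread (sd ≈ 2), a
property of interval estimation itself rather than of the detector —
detection recovers the ledgered event count to within 0.25% on every
seed.

`classification_experiment()` generates 2,000 mixed-class genes, corrupts
each independently with probability 1 − 0.589 (the error budget split
48/15/15/10/7/5 across indel, unannotated, split, missing, premature-stop
and merged classes, with infeasible draws falling back to indels so the
total stays exact), runs map → classify → summarize, and reports
percent-correct plus per-class recall against the ledger. On this synthetic
world the tests require per-class recall of at least 0.95 and a reported
percent-correct within the binomial 95% interval of the target error-free
fraction; the observed runs recover every class fully and report exactly
the realized injected fraction.

## Orthology, Venn partition and census statistics

`tiered_orthology()` pairs genes by reciprocal best local-alignment score
with two guards: identity floors (0.35 protein, 0.60 RNA) and a 5% score
margin over the runner-up, so equally scoring paralogs stay unpaired at the
sequence tiers. Unresolved genes fall back to RNA, then to relative
chromosomal location: a candidate is accepted when at least 2 of the 4
nearest already-paired flanking genes on each side agree co-linearly and
exactly one unpaired partner sits in the implied slot — ambiguous slots
stay unresolved rather than guessed. Gene families where 1:1 orthology is
not determinable (olfactory receptors, TCR/BCR, MHC) enter through an
exclusion list.

`venn_partition()` assigns every gene of the three species to exactly one
of the seven regions; the central region counts closed triangles (a gene's
two partners must themselves be partners). Open triangles are rare,
ill-defined cases; remaining pairs fill the two-species regions in the
fixed order PH, PM, MH, which makes the partition deterministic, and
per-species region sums reconstruct the universe sizes (asserted on every
call in the tests). `asymmetry_ratios()` reports PH/MH and the unique-gene
ratios, half-up to one decimal as such audits print them.

Domain architectures are compared by (name, rank-order) only —
`compare_architectures()` formalizes a side-by-side reading of annotation
graphics, where coordinates are not comparable across species but the
multiset of domains is. Readthrough evidence is scored 0–4; the two
boundary readings in the published wording overlap at "two other species
with pig transcription", which is resolved upward (category 4), and more
than two other species without pig evidence — not covered by the wording —
scores 2, keeping the function total. UTR conservation uses global
alignment per region with a 0.60 low-conservation threshold on either UTR
(no printed cutoff exists; the value is exposed and reported in output
headers). `orf_homology_search()` is a six-frame seeded scan used for
retroelement and microprotein censuses: a hit is intact only at full query
coverage with no internal stop; an internal stop, or a locus hit in two
different frames (the frameshift signature), marks it pseudogenized.

`over_representation()` is the generic fold-enrichment statistic — the
hypergeometric upper tail with Benjamini–Hochberg adjustment per
collection; it reproduces exhaustive enumeration exactly on small
universes. Reproducing any specific knowledgebase's term lists is out of
scope: results are defined relative to an explicit user-supplied
background.

## Worked example

```{r example, eval = FALSE}
truth <- generate_gene_models(sim_config(n_multi_exon = 80,
                                         n_selenoprotein = 10), seed = 1) |>
  emit_genome(seed = 1)
inj <- inject_build_errors(truth, error_profile(p_coding_indel = 0.2,
                                                p_unannotated = 0.1), seed = 1)
calls <- classify_build(truth, inj$build)
summarize_build(calls) |> glance()
recovery_stats(calls, inj$ledger)
```

## Known limitations

Uniform-random sequence understates repeat-induced ambiguity; the mapper
has no heuristic parity with BLAST scores or E-values; indels hugging
splice junctions are intrinsically hard to attribute (the injector avoids
them, the classifier catches most through the CDS-length frame check); the
synteny tier assumes gene order is meaningful, which tandem arrays violate;
and no re-annotation is attempted — the package audits an existing
annotation, it never creates one.
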