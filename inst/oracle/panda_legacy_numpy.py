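#!/usr/bin/env python
"""Independent numpy oracle for legacy PANDA message passing.

A direct transcription of the legacy message-passing equations
(T-normalisation with 1/sqrt(2) scaling, Tanimoto similarity kernel,
responsibility/availability averaging, diagonal refill
std * n * exp(2 * alpha * step), hamming = mean |W - (R + A) / 2|),
written against the published algorithm description and kept deliberately
separate from the R implementation so the two can be compared elementwise.

Usage:
  python panda_legacy_numpy.py MOTIF.tsv PPI.tsv COEXPR.tsv OUT.tsv \
      [alpha] [tolerance] [max_iter]

All three inputs are dense TSV matrices with a header row and a leading
row-name column; the output is written in the same layout.
"""
import sys

import numpy as np


def read_dense(path):
    with open(path) as fh:
        header = fh.readline().rstrip("\n").split("\t")[1:]
        rows, names = [], []
        for line in fh:
            parts = line.rstrip("\n").split("\t")
            names.append(parts[0])
            rows.append([float(x) for x in parts[1:]])
    return np.array(rows, dtype=float), names, header


def write_dense(path, M, row_names, col_names):
    with open(path, "w") as fh:
        fh.write("\t".join(["id"] + list(col_names)) + "\n")
        for name, row in zip(row_names, M):
            fh.write(name + "\t" + "\t".join(format(v, ".17g") for v in row) + "\n")


def t_normalize(M):
    rmu = M.mean(axis=1, keepdims=True)
    rsd = M.std(axis=1, keepdims=True)  # population std within each row
    cmu = M.mean(axis=0, keepdims=True)
    csd = M.std(axis=0, keepdims=True)
    with np.errstate(divide="ignore", invalid="ignore"):
        zr = np.where(rsd > 0, (M - rmu) / rsd, 0.0)
        zc = np.where(csd > 0, (M - cmu) / csd, 0.0)
    return (zr + zc) / np.sqrt(2.0)


def tanimoto(X, Y):
    A = X @ Y
    den = np.sqrt(np.maximum(
        np.square(X).sum(axis=1)[:, None] + np.square(Y).sum(axis=0)[None, :]
        - np.abs(A), 0.0))
    return A / np.maximum(den, 1e-10)


def legacy_diagonal(M, num, alpha, step):
    if num == 1:
        M[0, 0] = 0.0
        return M
    np.fill_diagonal(M, np.nan)
    mu = np.nanmean(M, axis=1)
    sd = np.sqrt(np.maximum(np.nanmean(M * M, axis=1) - mu * mu, 0.0))
    np.fill_diagonal(M, sd * num * np.exp(2.0 * alpha * step))
    return M


def panda_legacy(motif, ppi, coexpr, alpha=0.1, tolerance=0.001, max_iter=200):
    W = t_normalize(motif)
    P = t_normalize(ppi)
    C = t_normalize(coexpr)
    n_tfs, n_genes = W.shape
    hamming, step = np.inf, 0
    while hamming > tolerance and step < max_iter:
        R = tanimoto(P, W)
        A = tanimoto(W, C)
        RA = 0.5 * (R + A)
        hamming = np.abs(W - RA).mean()
        W = (1.0 - alpha) * W + alpha * RA
        if hamming > tolerance:
            P = (1.0 - alpha) * P + alpha * legacy_diagonal(
                tanimoto(W, W.T), n_tfs, alpha, step)
            C = (1.0 - alpha) * C + alpha * legacy_diagonal(
                tanimoto(W.T, W), n_genes, alpha, step)
        step += 1
    return W


def main(argv):
    motif_path, ppi_path, coexpr_path, out_path = argv[:4]
    alpha = float(argv[4]) if len(argv) > 4 else 0.1
    tolerance = float(argv[5]) if len(argv) > 5 else 0.001
    max_iter = int(argv[6]) if len(argv) > 6 else 200
    motif, tf_names, gene_names = read_dense(motif_path)
    ppi, _, _ = read_dense(ppi_path)
    coexpr, _, _ = read_dense(coexpr_path)
    W = panda_legacy(motif, ppi, coexpr, alpha, tolerance, max_iter)
    write_dense(out_path, W, tf_names, gene_names)


if __name__ == "__main__":
    main(sys.argv[1:])
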