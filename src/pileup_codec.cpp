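#include <Rcpp.h>
#include <vector>
#include <string>
#include <sstream>
#include <map>
using namespace Rcpp;

// Decoder / encoder for the samtools mpileup text dialect (all-positions
// variant).  Sources (aligned reference blocks or reads) are anonymous in the
// format; identity is reconstructed positionally: continuing sources keep
// their relative slot order between consecutive columns, '^' opens a new
// source at its slot, '$' closes one after the current column.  Violations of
// slot consistency are reported as errors, never guessed around.

struct EvRec {
  int source;
  int contig;
  int pos;
  int type;   // 1 = mismatch, 2 = insertion_after, 3 = deletion_next
  int len;
  std::string seq;
};

static void stop_at(int line, const std::string& msg) {
  std::ostringstream os;
  os << "mpileup line " << line << ": " << msg;
  stop(os.str());
}

// [[Rcpp::export(name = ".decode_pileup_cpp")]]
List decode_pileup_cpp(IntegerVector contig_idx, IntegerVector pos,
                       IntegerVector depth, CharacterVector bases) {
  int n = contig_idx.size();
  std::vector<EvRec> events;
  std::vector<int> cov_source, cov_contig, cov_start, cov_end;

  std::vector<int> active;        // source ids in slot order
  std::vector<int> active_start;  // start pos of each active source
  int next_id = 0;
  int cur_contig = -1, last_pos = -1;

  auto close_all = [&](int endpos) {
    for (size_t k = 0; k < active.size(); ++k) {
      cov_source.push_back(active[k]);
      cov_contig.push_back(cur_contig);
      cov_start.push_back(active_start[k]);
      cov_end.push_back(endpos);
    }
    active.clear();
    active_start.clear();
  };

  for (int i = 0; i < n; ++i) {
    int ci = contig_idx[i], p = pos[i], d = depth[i];
    if (ci != cur_contig) {
      if (cur_contig >= 0) close_all(last_pos);
      cur_contig = ci;
      last_pos = p - 1;
    }
    if (p != last_pos + 1)
      stop_at(i + 1, "positions not consecutive (all-positions pileup required)");
    last_pos = p;

    std::string bs = as<std::string>(bases[i]);
    if (d == 0) {
      if (!active.empty())
        stop_at(i + 1, "depth 0 while sources still open (slot inconsistency)");
      continue;  // "*" placeholder column
    }

    std::vector<int> new_active, new_start;
    std::vector<bool> ends;           // per-slot '$' flags
    std::vector<int> slot_src;
    size_t j = 0, prev_idx = 0;       // prev_idx walks the previous active list
    int slots = 0;

    while (j < bs.size()) {
      bool is_new = false;
      if (bs[j] == '^') {
        if (j + 1 >= bs.size()) stop_at(i + 1, "dangling '^'");
        j += 2;  // skip mapping-quality character
        is_new = true;
      }
      if (j >= bs.size()) stop_at(i + 1, "truncated base string");
      char c = bs[j];
      int src;
      if (is_new) {
        src = next_id++;
        new_active.push_back(src);
        new_start.push_back(p);
      } else {
        if (prev_idx >= active.size())
          stop_at(i + 1, "more continuing slots than open sources");
        src = active[prev_idx];
        new_active.push_back(src);
        new_start.push_back(active_start[prev_idx]);
        ++prev_idx;
      }
      ++slots;
      slot_src.push_back(src);

      switch (c) {
        case '.': case ',': case '*': case '>': case '<':
          break;
        case 'A': case 'C': case 'G': case 'T': case 'N':
        case 'a': case 'c': case 'g': case 't': case 'n': {
          EvRec e; e.source = src; e.contig = ci; e.pos = p; e.type = 1;
          e.len = 1; e.seq = std::string(1, (char)toupper(c));
          events.push_back(e);
          break;
        }
        default:
          stop_at(i + 1, std::string("unexpected base character '") + c + "'");
      }
      ++j;

      // trailing indel declaration(s)
      if (j < bs.size() && (bs[j] == '+' || bs[j] == '-')) {
        bool ins = bs[j] == '+';
        ++j;
        if (j >= bs.size() || !isdigit(bs[j])) stop_at(i + 1, "malformed indel length");
        int len = 0;
        while (j < bs.size() && isdigit(bs[j])) { len = len * 10 + (bs[j] - '0'); ++j; }
        if (len <= 0 || j + len > bs.size()) stop_at(i + 1, "indel length overruns base string");
        std::string seq = bs.substr(j, len);
        for (char& sc : seq) {
          if (!strchr("ACGTNacgtn", sc)) stop_at(i + 1, "non-nucleotide in indel sequence");
          sc = (char)toupper(sc);
        }
        j += len;
        EvRec e; e.source = src; e.contig = ci; e.pos = p;
        e.type = ins ? 2 : 3; e.len = len; e.seq = seq;
        events.push_back(e);
      }

      bool end_here = false;
      if (j < bs.size() && bs[j] == '$') { end_here = true; ++j; }
      ends.push_back(end_here);
    }

    if (slots != d)
      stop_at(i + 1, "decoded slot count does not match depth field");
    if (prev_idx != active.size())
      stop_at(i + 1, "open source missing from column (slot inconsistency)");

    // close sources flagged '$', keep the rest
    std::vector<int> keep, keep_start;
    for (size_t k = 0; k < new_active.size(); ++k) {
      if (ends[k]) {
        cov_source.push_back(new_active[k]);
        cov_contig.push_back(ci);
        cov_start.push_back(new_start[k]);
        cov_end.push_back(p);
      } else {
        keep.push_back(new_active[k]);
        keep_start.push_back(new_start[k]);
      }
    }
    active = keep;
    active_start = keep_start;
  }
  if (cur_contig >= 0) close_all(last_pos);

  for (size_t k = 0; k < cov_source.size(); ++k) cov_source[k] += 1;  // 1-based ids
  int ne = (int)events.size();
  IntegerVector e_src(ne), e_ctg(ne), e_pos(ne), e_type(ne), e_len(ne);
  CharacterVector e_seq(ne);
  for (int k = 0; k < ne; ++k) {
    e_src[k] = events[k].source + 1;
    e_ctg[k] = events[k].contig;
    e_pos[k] = events[k].pos;
    e_type[k] = events[k].type;
    e_len[k] = events[k].len;
    e_seq[k] = events[k].seq;
  }
  return List::create(
    _["cov"] = List::create(_["source"] = wrap(cov_source), _["contig"] = wrap(cov_contig),
                            _["start"] = wrap(cov_start), _["end"] = wrap(cov_end)),
    _["events"] = List::create(_["source"] = e_src, _["contig"] = e_ctg, _["pos"] = e_pos,
                               _["type"] = e_type, _["len"] = e_len, _["seq"] = e_seq),
    _["n_sources"] = next_id);
}

// [[Rcpp::export(name = ".encode_pileup_cpp")]]
CharacterVector encode_pileup_cpp(std::string contig_name, std::string draft_seq,
                                  IntegerVector cov_source, IntegerVector cov_start,
                                  IntegerVector cov_end,
                                  IntegerVector ev_source, IntegerVector ev_pos,
                                  IntegerVector ev_type, CharacterVector ev_seq) {
  int L = (int)draft_seq.size();
  int nc = cov_source.size();

  // per-position start/end hooks
  std::vector<std::vector<int>> starts(L + 2), run_end(L + 2);
  std::map<int, std::pair<int,int>> span;  // source -> (start,end)
  for (int k = 0; k < nc; ++k) {
    int s = cov_start[k], e = cov_end[k];
    if (s < 1 || e > L || e < s) stop("coverage run outside contig");
    starts[s].push_back(cov_source[k]);
    span[cov_source[k]] = std::make_pair(s, e);
  }

  // events keyed by (source, pos); deletion shadows (gap placeholders) computed
  std::map<std::pair<int,int>, std::string> mism;
  std::map<std::pair<int,int>, std::string> ins;
  std::map<std::pair<int,int>, int> del;
  std::map<std::pair<int,int>, bool> gap;
  int ne = ev_source.size();
  for (int k = 0; k < ne; ++k) {
    std::pair<int,int> key(ev_source[k], ev_pos[k]);
    std::string sq = as<std::string>(ev_seq[k]);
    if (ev_type[k] == 1) mism[key] = sq;
    else if (ev_type[k] == 2) ins[key] = sq;
    else {
      del[key] = (int)sq.size();
      for (int g = 1; g <= (int)sq.size(); ++g)
        gap[std::make_pair(ev_source[k], ev_pos[k] + g)] = true;
    }
  }

  std::vector<int> active;  // slot-ordered source ids
  CharacterVector out(L);
  for (int p = 1; p <= L; ++p) {
    for (int s : starts[p]) active.push_back(s);
    std::string bs;
    int d = (int)active.size();
    std::vector<int> keep;
    for (int s : active) {
      std::pair<int,int> key(s, p);
      if (span[s].first == p) bs += "^!";
      if (gap.count(key)) bs += '*';
      else if (mism.count(key)) bs += mism[key];
      else bs += '.';
      if (ins.count(key)) {
        bs += '+';
        bs += std::to_string((int)ins[key].size());
        bs += ins[key];
      } else if (del.count(key)) {
        std::string dseq = draft_seq.substr(p, del[key]);
        bs += '-';
        bs += std::to_string(del[key]);
        bs += dseq;
      }
      if (span[s].second == p) bs += '$';
      else keep.push_back(s);
    }
    active = keep;
    std::ostringstream line;
    char ref = draft_seq[p - 1];
    if (d == 0)
      line << contig_name << '\t' << p << '\t' << ref << "\t0\t*\t*";
    else
      line << contig_name << '\t' << p << '\t' << ref << '\t' << d << '\t'
           << bs << '\t' << std::string(d, '~');
    out[p - 1] = line.str();
  }
  return out;
}
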