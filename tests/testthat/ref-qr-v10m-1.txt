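% reference module grid: version 10-M byte-mode symbol, mask 0
% produced by an independent third-party encoder (reportlab.graphics.barcode.qrencoder,
% a port of Kazuhiko Arase's QR library) during development; frozen as a plain-text oracle
% payload: 0.0000,0.0000,0.0000,0.0000,0.0000,0.0000,0.0000,0.0000,0.0000,0.0000,0.0000,0.0000
#######..#.....##..##.##..#.#.#.#.###.###.#.####..#######
#.....#.#.###.####.#.#.#####..##...#...#.###.#.#..#.....#
#.###.#....###..#..#.###..##..#.##.#..#.##.#.###..#.###.#
#.###.#...##.#.#######.#...#.#..####.#..####...#..#.###.#
#.###.#.#.##.##.#....##.#.#####..#..#.#..#..#..#..#.###.#
#.....#..#.#..###.#...##.##...#.##.#.##.##..###...#.....#
#######.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#.#######
..........#.###...#.####.##...#..#..#.#..#....#.#........
#.#.#.#..##.#....###.#.#.######.###.#.#.###.#..##...#..#.
.#.###...#.##.#..#.#.#.#..##.#...#.#.#...#...#.#.#....###
...#..#.#####.#.##.#..#.#..#.#..###.##..###.##.####.#...#
####.#..##.#..#.##.#...#..##.#.#.#.#..###.##.#.#..##..##.
.####.#####.#.#...###.###.##.###..##....#..#..#.#..#..#.#
#........#####.#....#..#.#.###.###.##.##..####..#.####..#
......#####..#.#.#.##.######.###.#.#..#.#.##.#....##.##.#
#.##.#.#.####...#....#.#.#....#.##...#..##...#..##..##..#
..##..##.##..#.#.#.#.##.###.#...#.#.###.#.#.####..#.###.#
..#.#..##.###...##...##.##....##.#...#.#.#...#.#.#.#..#..
.#..###..##........##.....#.#.#.#...###.#...###..#..#...#
#.#..#.##.###.#...#####.##.#.#..#.##..##..#.#.#.##..#.#..
.##...#.#####..##.#.#..##..#.##.#..#...#....#.....#.#.#.#
#..#........##.##...##.#..####.##.###.####.#..##.#.#.#.#.
##....#.##.###.##.####.##..#.###..##..##.#.#..#.#...#.##.
.#..##.##.....####.##.##.#..##...#..#.#..#.###.#.#...#.##
.##...#...#.......#...##.#..#.#.###.#.#.###.#######.#..#.
.#.##....#.####...#.#.##..##.#...#.#.#...#.#.#.#.#....#..
..#######....#####...##.#######.###.##..###.#########...#
#..##...#.###.#.#....###.##...##..#.##.#..##.#.##...##...
#...#.#.#.#.#####..##.##.##.#.##....#.##...#..#.#.#.##..#
#####...#....##....#####..#...###.##.#.##.####.##...##..#
....#####.#.##...####.#.#.######..#.#..#..##.#..#######.#
#.####..#.#....#...###.#.#..#.#..#...#..##...#.##..#.#.#.
##.#.######.#.###..####.#.#...#.#.#.###.###.#.####..####.
##..##...##...#...##.##.####.#...#...#.#.#...#..###.#.#..
.##..##.#..##.##..#..#....#.#.#.#...###.###.##.#.#.....##
....#....###.####.##.#..#.##..#.#.##..#.#.##..##.#..#.##.
..##.##.###.##...#..######.###..#.##....#..#......###.#.#
###.##.###...###.##.#..#...#.#####.##.##.#.##.##...#.#.#.
...#####.##....##.#.#..##..###.#.#.#..#.##.#..#.#.######.
#.#.#..######.#..#.#.#.#...#.#.###...#...#.###.....#.#.##
#...#.#..#....###....#..##..#.#.###.###.#.#.###.#.##.###.
#.......#..#..#.....##..##..#..#.#...#...#.#.#.#.#.#..#..
##..#.#....#...######....##...#.###.###.##..###...#.#...#
##.##..##..#..##.##.##..###.#..#..#.##.#..#.#.#..###.#...
#.#####..##....#..#...##..####.#....#.##....#...##.#.#..#
######.......#.#.#.....#.#.#.####.##.#.##.##..####.#.#.#.
#.#..##...#.###.#....##.######.#..#.#..#..#.#.###.#.#.##.
#####..#.##..######.#.##.###.#...#..#.#..#...#.##.##.#.##
......#.##..####.#..##.#..#####.###.#...###.#.########.#.
........#.#.#.#....#.###.##...#..#.###...#...#.##...#.###
#######..#...##.##.#.##.###.#.#.####.#..###.##.##.#.#...#
#.....#...#.####..#.#..#.##...##..##..#.#.##.#..#...#.##.
#.###.#.#..#.##.#..###.##.######..##....#..#..#######.#.#
#.###.#..#....#...#..#.#...###.###.##.##..####....##.#.#.
#.###.#.###.######.##..###..#.##.#.#..#.#.##.#..#..#.##.#
#.....#..##..####....#.#.###.#.###...#..##...#....####.#.
#######.#..#########.##.##..##..#.#.###.#.#.###.#.##.####
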