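# Serum & plasma miRNA qPCR array panel (384-well layout abstracted away).
# Targets are the union of mature IDs observed in serum profiling plus
# synthetic placeholder assays (syn-miR-*) padding the panel to 372 targets.
name: serum_plasma_384HC
targets:
  - hsa-let-7a-3p
  - hsa-let-7a-5p
  - hsa-let-7b-5p
  - hsa-let-7c-5p
  - hsa-let-7d-3p
  - hsa-let-7d-5p
  - hsa-let-7e-5p
  - hsa-let-7f-5p
  - hsa-let-7g-5p
  - hsa-let-7i-5p
  - hsa-miR-1-3p
  - hsa-miR-100-5p
  - hsa-miR-101-3p
  - hsa-miR-106b-5p
  - hsa-miR-10a-5p
  - hsa-miR-10b-5p
  - hsa-miR-1180-3p
  - hsa-miR-1183
  - hsa-miR-1203
  - hsa-miR-1207-5p
  - hsa-miR-1225-3p
  - hsa-miR-1237-3p
  - hsa-miR-1247-5p
  - hsa-miR-125a-5p
  - hsa-miR-126-3p
  - hsa-miR-1260a
  - hsa-miR-1260b
  - hsa-miR-127-3p
  - hsa-miR-1281
  - hsa-miR-1287-5p
  - hsa-miR-1290
  - hsa-miR-1301-3p
  - hsa-miR-1307-3p
  - hsa-miR-130a-3p
  - hsa-miR-130b-3p
  - hsa-miR-130b-5p
  - hsa-miR-132-3p
  - hsa-miR-138-1-3p
  - hsa-miR-139-3p
  - hsa-miR-140-5p
  - hsa-miR-142-5p
  - hsa-miR-144-3p
  - hsa-miR-146a-5p
  - hsa-miR-146b-5p
  - hsa-miR-150-5p
  - hsa-miR-151a-3p
  - hsa-miR-151a-5p
  - hsa-miR-151b
  - hsa-miR-152-3p
  - hsa-miR-1539
  - hsa-miR-154-5p
  - hsa-miR-1587
  - hsa-miR-15a-5p
  - hsa-miR-15b-5p
  - hsa-miR-16-5p
  - hsa-miR-181a-5p
  - hsa-miR-181c-3p
  - hsa-miR-181c-5p
  - hsa-miR-181d-5p
  - hsa-miR-185-5p
  - hsa-miR-186-5p
  - hsa-miR-188-5p
  - hsa-miR-18a-3p
  - hsa-miR-18a-5p
  - hsa-miR-1909-5p
  - hsa-miR-190a-5p
  - hsa-miR-191-5p
  - hsa-miR-1910-5p
  - hsa-miR-1913
  - hsa-miR-192-5p
  - hsa-miR-193a-5p
  - hsa-miR-193b-3p
  - hsa-miR-194-5p
  - hsa-miR-195-5p
  - hsa-miR-1976
  - hsa-miR-199a-5p
  - hsa-miR-199b-3p
  - hsa-miR-199b-5p
  - hsa-miR-19a-3p
  - hsa-miR-19b-3p
  - hsa-miR-206
  - hsa-miR-20b-5p
  - hsa-miR-21-5p
  - hsa-miR-210-3p
  - hsa-miR-2110
  - hsa-miR-219a-1-3p
  - hsa-miR-223-3p
  - hsa-miR-224-5p
  - hsa-miR-2276-3p
  - hsa-miR-23a-3p
  - hsa-miR-24-3p
  - hsa-miR-2467-3p
  - hsa-miR-25-3p
  - hsa-miR-26b-3p
  - hsa-miR-26b-5p
  - hsa-miR-27b-3p
  - hsa-miR-28-3p
  - hsa-miR-28-5p
  - hsa-miR-29b-3p
  - hsa-miR-301a-3p
  - hsa-miR-30a-3p
  - hsa-miR-30e-3p
  - hsa-miR-3131
  - hsa-miR-3135b
  - hsa-miR-3141
  - hsa-miR-3176
  - hsa-miR-3183
  - hsa-miR-3185
  - hsa-miR-3191-3p
  - hsa-miR-3200-5p
  - hsa-miR-320a
  - hsa-miR-320e
  - hsa-miR-324-3p
  - hsa-miR-324-5p
  - hsa-miR-328-3p
  - hsa-miR-330-3p
  - hsa-miR-331-3p
  - hsa-miR-338-3p
  - hsa-miR-339-3p
  - hsa-miR-339-5p
  - hsa-miR-340-5p
  - hsa-miR-342-3p
  - hsa-miR-345-5p
  - hsa-miR-34a-5p
  - hsa-miR-34c-3p
  - hsa-miR-361-3p
  - hsa-miR-361-5p
  - hsa-miR-3610
  - hsa-miR-3622a-5p
  - hsa-miR-363-3p
  - hsa-miR-3646
  - hsa-miR-3651
  - hsa-miR-3653-3p
  - hsa-miR-365b-3p
  - hsa-miR-370-3p
  - hsa-miR-373-5p
  - hsa-miR-374a-5p
  - hsa-miR-374c-5p
  - hsa-miR-375
  - hsa-miR-376c-3p
  - hsa-miR-378a-3p
  - hsa-miR-378a-5p
  - hsa-miR-378b
  - hsa-miR-378e
  - hsa-miR-378g
  - hsa-miR-382-5p
  - hsa-miR-3907
  - hsa-miR-3911
  - hsa-miR-3923
  - hsa-miR-409-3p
  - hsa-miR-421
  - hsa-miR-423-5p
  - hsa-miR-424-3p
  - hsa-miR-425-3p
  - hsa-miR-425-5p
  - hsa-miR-4258
  - hsa-miR-4267
  - hsa-miR-4274
  - hsa-miR-4291
  - hsa-miR-4301
  - hsa-miR-4302
  - hsa-miR-4306
  - hsa-miR-4323
  - hsa-miR-433-3p
  - hsa-miR-4422
  - hsa-miR-4454
  - hsa-miR-4505
  - hsa-miR-4516
  - hsa-miR-451a
  - hsa-miR-4538
  - hsa-miR-454-3p
  - hsa-miR-4651
  - hsa-miR-4687-5p
  - hsa-miR-4688
  - hsa-miR-4689
  - hsa-miR-4732-3p
  - hsa-miR-4732-5p
  - hsa-miR-484
  - hsa-miR-485-5p
  - hsa-miR-487b-3p
  - hsa-miR-489-3p
  - hsa-miR-490-3p
  - hsa-miR-501-5p
  - hsa-miR-502-3p
  - hsa-miR-505-3p
  - hsa-miR-5095
  - hsa-miR-523-5p
  - hsa-miR-548o-5p
  - hsa-miR-550a-5p
  - hsa-miR-574-3p
  - hsa-miR-590-5p
  - hsa-miR-596
  - hsa-miR-598-3p
  - hsa-miR-605-5p
  - hsa-miR-625-3p
  - hsa-miR-627-5p
  - hsa-miR-628-3p
  - hsa-miR-629-5p
  - hsa-miR-664a-3p
  - hsa-miR-671-3p
  - hsa-miR-675-3p
  - hsa-miR-7-1-3p
  - hsa-miR-7-2-3p
  - hsa-miR-7-5p
  - hsa-miR-769-5p
  - hsa-miR-874-3p
  - hsa-miR-877-3p
  - hsa-miR-877-5p
  - hsa-miR-92a-3p
  - hsa-miR-92b-3p
  - hsa-miR-93-3p
  - hsa-miR-93-5p
  - hsa-miR-942-5p
  - hsa-miR-99a-5p
  - syn-miR-001
  - syn-miR-002
  - syn-miR-003
  - syn-miR-004
  - syn-miR-005
  - syn-miR-006
  - syn-miR-007
  - syn-miR-008
  - syn-miR-009
  - syn-miR-010
  - syn-miR-011
  - syn-miR-012
  - syn-miR-013
  - syn-miR-014
  - syn-miR-015
  - syn-miR-016
  - syn-miR-017
  - syn-miR-018
  - syn-miR-019
  - syn-miR-020
  - syn-miR-021
  - syn-miR-022
  - syn-miR-023
  - syn-miR-024
  - syn-miR-025
  - syn-miR-026
  - syn-miR-027
  - syn-miR-028
  - syn-miR-029
  - syn-miR-030
  - syn-miR-031
  - syn-miR-032
  - syn-miR-033
  - syn-miR-034
  - syn-miR-035
  - syn-miR-036
  - syn-miR-037
  - syn-miR-038
  - syn-miR-039
  - syn-miR-040
  - syn-miR-041
  - syn-miR-042
  - syn-miR-043
  - syn-miR-044
  - syn-miR-045
  - syn-miR-046
  - syn-miR-047
  - syn-miR-048
  - syn-miR-049
  - syn-miR-050
  - syn-miR-051
  - syn-miR-052
  - syn-miR-053
  - syn-miR-054
  - syn-miR-055
  - syn-miR-056
  - syn-miR-057
  - syn-miR-058
  - syn-miR-059
  - syn-miR-060
  - syn-miR-061
  - syn-miR-062
  - syn-miR-063
  - syn-miR-064
  - syn-miR-065
  - syn-miR-066
  - syn-miR-067
  - syn-miR-068
  - syn-miR-069
  - syn-miR-070
  - syn-miR-071
  - syn-miR-072
  - syn-miR-073
  - syn-miR-074
  - syn-miR-075
  - syn-miR-076
  - syn-miR-077
  - syn-miR-078
  - syn-miR-079
  - syn-miR-080
  - syn-miR-081
  - syn-miR-082
  - syn-miR-083
  - syn-miR-084
  - syn-miR-085
  - syn-miR-086
  - syn-miR-087
  - syn-miR-088
  - syn-miR-089
  - syn-miR-090
  - syn-miR-091
  - syn-miR-092
  - syn-miR-093
  - syn-miR-094
  - syn-miR-095
  - syn-miR-096
  - syn-miR-097
  - syn-miR-098
  - syn-miR-099
  - syn-miR-100
  - syn-miR-101
  - syn-miR-102
  - syn-miR-103
  - syn-miR-104
  - syn-miR-105
  - syn-miR-106
  - syn-miR-107
  - syn-miR-108
  - syn-miR-109
  - syn-miR-110
  - syn-miR-111
  - syn-miR-112
  - syn-miR-113
  - syn-miR-114
  - syn-miR-115
  - syn-miR-116
  - syn-miR-117
  - syn-miR-118
  - syn-miR-119
  - syn-miR-120
  - syn-miR-121
  - syn-miR-122
  - syn-miR-123
  - syn-miR-124
  - syn-miR-125
  - syn-miR-126
  - syn-miR-127
  - syn-miR-128
  - syn-miR-129
  - syn-miR-130
  - syn-miR-131
  - syn-miR-132
  - syn-miR-133
  - syn-miR-134
  - syn-miR-135
  - syn-miR-136
  - syn-miR-137
  - syn-miR-138
  - syn-miR-139
  - syn-miR-140
  - syn-miR-141
  - syn-miR-142
  - syn-miR-143
  - syn-miR-144
  - syn-miR-145
  - syn-miR-146
  - syn-miR-147
  - syn-miR-148
  - syn-miR-149
  - syn-miR-150
  - syn-miR-151
  - syn-miR-152
  - syn-miR-153
  - syn-miR-154
  - syn-miR-155
  - syn-miR-156
  - syn-miR-157
  - syn-miR-158
endogenous_controls:
  - SNORD61
  - SNORD68
  - SNORD72
  - SNORD95
  - SNORD96A
  - RNU6B
spike_in: cel-miR-39
hemolysis_pair:
  - hsa-miR-23a-3p
  - hsa-miR-451a
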