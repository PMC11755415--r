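"timestamp","value"
"2019-04-11 08:00:00",68
"2019-04-11 08:01:00",78
"2019-04-11 08:02:00",75
"2019-04-11 08:03:00",75
"2019-04-11 08:04:00",85
"2019-04-11 08:05:00",79
"2019-04-11 08:06:00",86
"2019-04-11 08:07:00",78
"2019-04-11 08:08:00",82
"2019-04-11 08:09:00",84
"2019-04-11 08:10:00",89
"2019-04-11 08:11:00",92
"2019-04-11 08:12:00",91
"2019-04-11 08:13:00",88
"2019-04-11 08:14:00",94
"2019-04-11 08:15:00",89
"2019-04-11 08:16:00",88
"2019-04-11 08:17:00",101
"2019-04-11 08:18:00",96
"2019-04-11 08:19:00",90
"2019-04-11 08:20:00",103
"2019-04-11 08:21:00",89
"2019-04-11 08:22:00",96
"2019-04-11 08:23:00",104
"2019-04-11 08:24:00",92
"2019-04-11 08:25:00",102
"2019-04-11 08:26:00",98
"2019-04-11 08:27:00",112
"2019-04-11 08:28:00",91
"2019-04-11 08:29:00",102
"2019-04-11 08:30:00",110
"2019-04-11 08:31:00",99
"2019-04-11 08:32:00",105
"2019-04-11 08:33:00",103
"2019-04-11 08:34:00",108
"2019-04-11 08:35:00",92
"2019-04-11 08:36:00",120
"2019-04-11 08:37:00",89
"2019-04-11 08:38:00",99
"2019-04-11 08:39:00",97
"2019-04-11 08:40:00",104
"2019-04-11 08:41:00",114
"2019-04-11 08:42:00",99
"2019-04-11 08:43:00",96
"2019-04-11 08:44:00",101
"2019-04-11 08:45:00",102
"2019-04-11 08:46:00",106
"2019-04-11 08:47:00",107
"2019-04-11 08:48:00",109
"2019-04-11 08:49:00",102
"2019-04-11 08:50:00",111
"2019-04-11 08:51:00",97
"2019-04-11 08:52:00",96
"2019-04-11 08:53:00",98
"2019-04-11 08:54:00",110
"2019-04-11 08:55:00",97
"2019-04-11 08:56:00",91
"2019-04-11 08:57:00",102
"2019-04-11 08:58:00",89
"2019-04-11 08:59:00",97
"2019-04-11 09:00:00",99
"2019-04-11 09:01:00",95
"2019-04-11 09:02:00",91
"2019-04-11 09:03:00",97
"2019-04-11 09:04:00",83
"2019-04-11 09:05:00",96
"2019-04-11 09:06:00",92
"2019-04-11 09:07:00",86
"2019-04-11 09:08:00",79
"2019-04-11 09:09:00",80
"2019-04-11 09:10:00",83
"2019-04-11 09:11:00",86
"2019-04-11 09:12:00",86
"2019-04-11 09:13:00",87
"2019-04-11 09:14:00",70
"2019-04-11 09:15:00",83
"2019-04-11 09:16:00",74
"2019-04-11 09:17:00",83
"2019-04-11 09:18:00",65
"2019-04-11 09:19:00",76
"2019-04-11 09:20:00",73
"2019-04-11 09:21:00",68
"2019-04-11 09:22:00",74
"2019-04-11 09:23:00",61
"2019-04-11 09:24:00",77
"2019-04-11 09:25:00",68
"2019-04-11 09:26:00",80
"2019-04-11 09:27:00",70
"2019-04-11 09:28:00",70
"2019-04-11 09:29:00",66
"2019-04-11 09:30:00",60
"2019-04-11 09:31:00",68
"2019-04-11 09:32:00",57
"2019-04-11 09:33:00",52
"2019-04-11 09:34:00",52
"2019-04-11 09:35:00",64
"2019-04-11 09:36:00",53
"2019-04-11 09:37:00",67
"2019-04-11 09:38:00",56
"2019-04-11 09:39:00",56
"2019-04-11 09:40:00",60
"2019-04-11 09:41:00",69
"2019-04-11 09:42:00",61
"2019-04-11 09:43:00",54
"2019-04-11 09:44:00",55
"2019-04-11 09:45:00",57
"2019-04-11 09:46:00",57
"2019-04-11 09:47:00",52
"2019-04-11 09:48:00",52
"2019-04-11 09:49:00",54
"2019-04-11 09:50:00",52
"2019-04-11 09:51:00",52
"2019-04-11 09:52:00",52
"2019-04-11 09:53:00",52
"2019-04-11 09:54:00",52
"2019-04-11 09:55:00",54
"2019-04-11 09:56:00",55
"2019-04-11 09:57:00",55
"2019-04-11 09:58:00",52
"2019-04-11 09:59:00",52
"2019-04-11 10:00:00",52
"2019-04-11 10:01:00",52
"2019-04-11 10:02:00",63
"2019-04-11 10:03:00",52
"2019-04-11 10:04:00",58
"2019-04-11 10:05:00",52
"2019-04-11 10:06:00",55
"2019-04-11 10:07:00",55
"2019-04-11 10:08:00",52
"2019-04-11 10:09:00",52
"2019-04-11 10:10:00",60
"2019-04-11 10:11:00",52
"2019-04-11 10:12:00",52
"2019-04-11 10:13:00",52
"2019-04-11 10:14:00",58
"2019-04-11 10:15:00",56
"2019-04-11 10:16:00",55
"2019-04-11 10:17:00",55
"2019-04-11 10:18:00",60
"2019-04-11 10:19:00",63
"2019-04-11 10:20:00",66
"2019-04-11 10:21:00",61
"2019-04-11 10:22:00",58
"2019-04-11 10:23:00",62
"2019-04-11 10:24:00",63
"2019-04-11 10:25:00",55
"2019-04-11 10:26:00",57
"2019-04-11 10:27:00",61
"2019-04-11 10:28:00",55
"2019-04-11 10:29:00",62
"2019-04-11 10:30:00",68
"2019-04-11 10:31:00",65
"2019-04-11 10:32:00",61
"2019-04-11 10:33:00",62
"2019-04-11 10:34:00",75
"2019-04-11 10:35:00",63
"2019-04-11 10:36:00",65
"2019-04-11 10:37:00",79
"2019-04-11 10:38:00",65
"2019-04-11 10:39:00",75
"2019-04-11 10:40:00",85
"2019-04-11 10:41:00",77
"2019-04-11 10:42:00",84
"2019-04-11 10:43:00",81
"2019-04-11 10:44:00",82
"2019-04-11 10:45:00",72
"2019-04-11 10:46:00",89
"2019-04-11 10:47:00",70
"2019-04-11 10:48:00",86
"2019-04-11 10:49:00",90
"2019-04-11 10:50:00",75
"2019-04-11 10:51:00",87
"2019-04-11 10:52:00",77
"2019-04-11 10:53:00",89
"2019-04-11 10:54:00",96
"2019-04-11 10:55:00",86
"2019-04-11 10:56:00",98
"2019-04-11 10:57:00",98
"2019-04-11 10:58:00",87
"2019-04-11 10:59:00",94
"2019-04-11 11:00:00",99
"2019-04-11 11:01:00",95
"2019-04-11 11:02:00",93
"2019-04-11 11:03:00",97
"2019-04-11 11:04:00",97
"2019-04-11 11:05:00",107
"2019-04-11 11:06:00",100
"2019-04-11 11:07:00",94
"2019-04-11 11:08:00",112
"2019-04-11 11:09:00",97
"2019-04-11 11:10:00",104
"2019-04-11 11:11:00",104
"2019-04-11 11:12:00",99
"2019-04-11 11:13:00",100
"2019-04-11 11:14:00",103
"2019-04-11 11:15:00",101
"2019-04-11 11:16:00",106
"2019-04-11 11:17:00",117
"2019-04-11 11:18:00",87
"2019-04-11 11:19:00",102
"2019-04-11 11:20:00",108
"2019-04-11 11:21:00",104
"2019-04-11 11:22:00",94
"2019-04-11 11:23:00",102
"2019-04-11 11:24:00",107
"2019-04-11 11:25:00",110
"2019-04-11 11:26:00",96
"2019-04-11 11:27:00",94
"2019-04-11 11:28:00",92
"2019-04-11 11:29:00",97
"2019-04-11 11:30:00",100
"2019-04-11 11:31:00",105
"2019-04-11 11:32:00",87
"2019-04-11 11:33:00",96
"2019-04-11 11:34:00",96
"2019-04-11 11:35:00",89
"2019-04-11 11:36:00",107
"2019-04-11 11:37:00",89
"2019-04-11 11:38:00",92
"2019-04-11 11:39:00",88
"2019-04-11 11:40:00",98
"2019-04-11 11:41:00",102
"2019-04-11 11:42:00",91
"2019-04-11 11:43:00",99
"2019-04-11 11:44:00",84
"2019-04-11 11:45:00",80
"2019-04-11 11:46:00",80
"2019-04-11 11:47:00",95
"2019-04-11 11:48:00",91
"2019-04-11 11:49:00",85
"2019-04-11 11:50:00",88
"2019-04-11 11:51:00",76
"2019-04-11 11:52:00",82
"2019-04-11 11:53:00",81
"2019-04-11 11:54:00",89
"2019-04-11 11:55:00",76
"2019-04-11 11:56:00",72
"2019-04-11 11:57:00",66
"2019-04-11 11:58:00",78
"2019-04-11 11:59:00",80
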